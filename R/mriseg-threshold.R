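#' Fat/muscle threshold from 5-component k-means
#'
#' Clusters the internal-compartment intensities with 1-D k-means (k = 5 by
#' default, several seeded restarts, best inertia kept) and derives the fat
#' threshold from the clustering. Two readings of "the median value of the
#' clustering" are provided:
#' \describe{
#'   \item{`"gap"` (default)}{the midpoint across the widest gap between
#'     consecutive sorted centres. Muscle and fat form well-separated
#'     intensity modes while k-means tiles each mode with however many
#'     clusters its mass earns, so the widest inter-centre gap is the
#'     muscle/fat divide regardless of how the five clusters split between
#'     the modes.}
#'   \item{`"median_center"`}{the middle sorted cluster centre itself, the
#'     most literal reading. When one tissue dominates the compartment this
#'     sits inside that tissue's intensity mode rather than between tissues,
#'     so the segmentation pipeline does not use it.}
#' }
#' Both are translation-equivariant: shifting all intensities by a constant
#' shifts the threshold by the same constant.
#'
#' @param intensities numeric vector of internal-compartment voxel values.
#' @param k number of clusters.
#' @param seed integer seed (threshold is deterministic given the seed).
#' @param n_restarts k-means restarts.
#' @param method threshold rule, see Details.
#' @return the threshold intensity.
#' @export
kmeans_threshold <- function(intensities, k = 5L, seed = 1L, n_restarts = 10L,
                             method = c("gap", "median_center")) {
  method <- match.arg(method)
  intensities <- intensities[is.finite(intensities)]
  if (length(unique(intensities)) < k)
    stop("need at least ", k, " distinct intensities for ", k, "-means")
  set.seed(seed)
  km <- stats::kmeans(intensities, centers = k, nstart = n_restarts,
                      iter.max = 100)
  centers <- sort(km$centers[, 1])
  if (method == "median_center" || k < 2) return(unname(centers[ceiling(k / 2)]))
  g <- which.max(diff(centers))
  unname((centers[g] + centers[g + 1]) / 2)
}

#' Threshold the internal compartment into a fat depot mask
#'
#' Voxels of the internal compartment whose intensity exceeds the threshold,
#' minus any exclusion masks (manually segmented liver, separately delineated
#' bone marrow). The internal compartment must not overlap the SAT mask when
#' one is supplied.
#'
#' @param volume the (bias-corrected) MRI `image_volume`.
#' @param internal_mask logical/0-1 array: the muscular/abdominal compartment.
#' @param threshold intensity cut from [kmeans_threshold()].
#' @param exclusion_masks list of logical/0-1 arrays removed from the result.
#' @param sat_mask optional SAT mask; overlap with `internal_mask` is an error.
#' @return logical array: the depot mask.
#' @export
segment_internal_fat <- function(volume, internal_mask, threshold,
                                 exclusion_masks = list(), sat_mask = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  internal <- internal_mask > 0
  if (!is.null(sat_mask) && any(internal & (sat_mask > 0)))
    stop("internal compartment overlaps the SAT mask")
  fat <- internal & (volume$voxels > threshold)
  for (ex in exclusion_masks) fat <- fat & !(ex > 0)
  fat
}
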