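#' Anatomical slice-range selection for a depot
#'
#' Applies the study's anatomical delimiter rules to labeled landmark slice
#' indices (slices numbered head-to-foot):
#' \itemize{
#'   \item visceral: from the slice containing the Th11/Th12 disc down to the
#'     most distal slice without the iliac crest (`iliac_crest_first - 1`);
#'   \item abdominal SAT: from the Th12/L1 disc down to the last slice not
#'     including the caput femoris;
#'   \item femoral depots (femoral SAT, inter-muscular fat, bone marrow): from
#'     the lower delimitation of the gluteal fat down to the last slice
#'     without the patella.
#' }
#'
#' @param landmarks named list/vector of slice indices; recognised names:
#'   `th11_th12_disc`, `iliac_crest_first`, `th12_l1_disc`,
#'   `caput_femoris_first`, `gluteal_lower`, `patella_first`.
#' @param depot one of `"visceral"`, `"abdominal_sat"`, `"femoral_sat"`,
#'   `"inter_muscular"`, `"bone_marrow"`.
#' @param n_slices optional volume slice count for bounds checking.
#' @return list with `first`, `last` (inclusive) and `n_slices_analyzed`.
#' @export
select_slices <- function(landmarks, depot = c("visceral", "abdominal_sat",
                                               "femoral_sat", "inter_muscular",
                                               "bone_marrow"),
                          n_slices = NULL) {
  depot <- match.arg(depot)
  need <- switch(depot,
    visceral = c("th11_th12_disc", "iliac_crest_first"),
    abdominal_sat = c("th12_l1_disc", "caput_femoris_first"),
    c("gluteal_lower", "patella_first"))
  missing_lm <- setdiff(need, names(landmarks))
  if (length(missing_lm))
    stop("missing landmark(s) for depot '", depot, "': ",
         paste(missing_lm, collapse = ", "))
  upper <- as.integer(landmarks[[need[1]]])
  lower <- as.integer(landmarks[[need[2]]]) - 1L   # last slice WITHOUT the structure
  if (upper > lower)
    stop("upper landmark (slice ", upper, ") lies below lower bound (slice ",
         lower, ")")
  if (!is.null(n_slices) && (upper < 1L || lower > n_slices))
    stop("slice range ", upper, "..", lower, " exceeds the volume (",
         n_slices, " slices)")
  list(first = upper, last = lower, n_slices_analyzed = lower - upper + 1L)
}

#' Convert a depot mask to volume and mass
#'
#' `volume_L = n_voxels * pixel_x * pixel_y * slice_pitch / 1e6`, and
#' `mass_kg = volume_L * 0.9` (adipose density 0.9 kg/L), exactly. The slice
#' pitch (centre-to-centre) is used so the stack integrates contiguous
#' anatomy.
#'
#' @param mask logical/0-1 3-D array (or `image_volume`).
#' @param spacing_mm length-3 spacing; taken from the volume when `mask` is
#'   an `image_volume`.
#' @param depot depot name carried through to the result.
#' @param slice_range optional result of [select_slices()]; when given, only
#'   voxels inside the range are counted and `n_slices_analyzed` is recorded.
#' @return a `depot_mass`: `depot`, `volume_L`, `mass_kg`,
#'   `n_slices_analyzed`, `n_voxels`.
#' @export
mask_to_mass <- function(mask, spacing_mm = NULL, depot = "depot",
                         slice_range = NULL) {
  if (inherits(mask, "image_volume")) {
    spacing_mm <- mask$spacing_mm
    mask <- mask$voxels
  }
  if (is.null(spacing_mm)) stop("spacing_mm required for a bare array mask")
  arr <- mask > 0
  n_sl <- if (length(dim(arr)) == 3L) dim(arr)[3] else 1L
  if (!is.null(slice_range)) {
    keep <- array(FALSE, dim(arr))
    keep[, , slice_range$first:slice_range$last] <- TRUE
    arr <- arr & keep
    n_sl <- slice_range$n_slices_analyzed
  }
  n_vox <- sum(arr)
  vol_L <- n_vox * prod(spacing_mm) * 1e-6
  structure(list(depot = depot, volume_L = vol_L,
                 mass_kg = vol_L * ADIPOSE_DENSITY_KG_PER_L,
                 n_slices_analyzed = n_sl, n_voxels = n_vox),
            class = "depot_mass")
}

#' @export
print.depot_mass <- function(x, ...) {
  cat(sprintf("<depot_mass> %s: %.4f L = %.4f kg (%d voxels, %d slices)\n",
              x$depot, x$volume_L, x$mass_kg, x$n_voxels,
              x$n_slices_analyzed))
  invisible(x)
}
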