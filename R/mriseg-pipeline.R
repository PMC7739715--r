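#' Full automated MRI adipose segmentation of one volume
#'
#' Chains the whole analysis the way the in-house tooling it reproduces did:
#' bias correction, per-slice body masking, polar unrolling around the body
#' centroid, minimal-path detection of the outer (skin) and inner
#' (SAT/internal) boundaries, SAT rasterisation, 5-component k-means-median
#' thresholding of the internal compartment, exclusion of supplied liver /
#' bone-marrow masks, and volume-to-mass conversion at 0.9 kg/L.
#'
#' @param mri an MRI `image_volume`.
#' @param exclusion_masks named list of 0/1 arrays removed from the internal
#'   fat depot (e.g. `liver`, `bone_marrow`).
#' @param delta boundary smoothness constraint (radial samples per angle).
#' @param n_angles angle columns used for unrolling.
#' @param seed seed for the k-means restarts.
#' @param slice_range optional [select_slices()] result restricting the
#'   analysis.
#' @param correct_bias_first set `FALSE` if the volume is already corrected.
#' @return list with `sat_mask`, `internal_fat_mask` (logical arrays),
#'   `threshold`, `masses` (list of `depot_mass`), `boundaries` (per slice).
#' @export
segment_adipose_mri <- function(mri, exclusion_masks = list(), delta = 2L,
                                n_angles = 360L, seed = 1L,
                                slice_range = NULL,
                                correct_bias_first = TRUE) {
  stopifnot(inherits(mri, "image_volume"))
  corrected <- if (correct_bias_first) correct_bias(mri) else mri
  bmask <- body_mask(corrected)
  d <- dim(corrected$voxels)
  sat <- array(FALSE, d)
  internal <- array(FALSE, d)
  boundaries <- vector("list", d[3])
  slices <- if (is.null(slice_range)) seq_len(d[3])
            else slice_range$first:slice_range$last

  for (z in slices) {
    msk <- bmask$voxels[, , z]
    if (!any(msk > 0)) next
    ctr <- colMeans(which(msk > 0, arr.ind = TRUE))   # body-mask centroid
    pol <- unroll_slice(corrected$voxels[, , z], ctr, n_angles = n_angles,
                        spacing_mm = corrected$spacing_mm[1:2])
    pol_m <- unroll_slice(msk, ctr, n_angles = n_angles,
                          spacing_mm = corrected$spacing_mm[1:2])
    b <- detect_sat_boundaries(pol, pol_m, delta = delta)
    boundaries[[z]] <- b
    sat_sl <- sat_mask_from_boundaries(b$outer, b$inner, pol)
    sat[, , z] <- sat_sl & (msk > 0)
    # internal compartment: inside the inner boundary
    inner_only <- sat_mask_from_boundaries(
      b$inner,
      boundary_curve(rep(1L, n_angles), pol$radial_step_mm, b$inner$smoothness_delta),
      pol)
    internal[, , z] <- (inner_only | near_centre(pol, d[1:2])) & (msk > 0) & !sat_sl
  }

  excl_total <- array(FALSE, d)
  for (m in exclusion_masks) excl_total <- excl_total | (m > 0)
  vals <- corrected$voxels[internal & !excl_total]
  threshold <- kmeans_threshold(vals, k = 5L, seed = seed)
  fat <- segment_internal_fat(corrected, internal, threshold,
                              exclusion_masks = exclusion_masks,
                              sat_mask = sat)
  masses <- list(
    sat = mask_to_mass(sat, corrected$spacing_mm, "sat", slice_range),
    internal_fat = mask_to_mass(fat, corrected$spacing_mm, "internal_fat",
                                slice_range)
  )
  list(sat_mask = sat, internal_fat_mask = fat, internal_mask = internal,
       threshold = threshold, masses = masses, boundaries = boundaries,
       corrected = corrected, body_mask = bmask)
}

# pixels closer to the centre than the first radial sample ring
near_centre <- function(pol, d) {
  xg <- (matrix(seq_len(d[1]), d[1], d[2]) - pol$center_px[1]) * pol$spacing_mm[1]
  yg <- (matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - pol$center_px[2]) *
    pol$spacing_mm[2]
  sqrt(xg^2 + yg^2) <= pol$radial_step_mm
}
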