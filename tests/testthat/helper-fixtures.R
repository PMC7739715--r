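# shared fixtures, all generated in code

# clean annulus phantom: no organs, no internal fat, no noise/bias
annulus_phantom <- function(n_slices = 1, inner = 80, outer = 95, seed = 7) {
  spec <- phantom_spec(n_slices = n_slices, body_radius_mm = outer,
                       sat_thickness_mm = outer - inner,
                       internal_fat_fraction = 0, organ_layout = list(),
                       noise_sd = 0, bias_amplitude = 0, seed = seed)
  generate_phantom(spec, region = "abdomen")
}

default_schedule <- function() build_frame_schedule()

default_input <- function(t_max = 60, by = 0.05) {
  simulate_input_function(times_min = seq(0, t_max, by = by))
}

# unroll one slice around its body-mask centroid
unroll_phantom_slice <- function(phantom, z = 1, n_angles = 360) {
  msk <- body_mask(phantom$mri)$voxels[, , z]
  ctr <- colMeans(which(msk > 0, arr.ind = TRUE))
  sp <- phantom$mri$spacing_mm[1:2]
  list(
    pol = unroll_slice(phantom$mri$voxels[, , z], ctr, n_angles = n_angles,
                       spacing_mm = sp),
    pol_mask = unroll_slice(msk, ctr, n_angles = n_angles, spacing_mm = sp),
    mask = msk, center = ctr
  )
}
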