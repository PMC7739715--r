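#' Generate an MRI + CT phantom with ground-truth depot masses
#'
#' Builds a synthetic axial volume pair emulating the scans the segmentation
#' chain consumes: a water-suppressed-T1-like MRI (fat bright, muscle mid,
#' background dark) and a low-dose-CT-like Hounsfield map (adipose voxels in
#' \[-150, -50\] HU, everything else outside that range), together with the
#' exact voxel labels and depot masses.
#'
#' The body is a disc of radius `body_radius_mm`; the SAT annulus occupies
#' the outer `sat_thickness_mm` of it (thickness may vary with angle); the
#' internal compartment carries muscle plus scattered circular fat islands
#' (visceral fat in the abdomen, inter-muscular fat in the thigh) and any
#' organs from `organ_layout`. For `region = "abdomen"` a default liver
#' ellipse is placed in the upper slices unless `organ_layout` says otherwise;
#' for `region = "thigh"` a central bone-marrow disc is added.
#'
#' Ground-truth masses satisfy, exactly,
#' `mass_kg = n_voxels * voxel_volume_L * 0.9`.
#'
#' @param spec a [phantom_spec()].
#' @param region `"abdomen"` or `"thigh"`; selects the default organ layout
#'   and the name of the scattered internal depot.
#' @return A list with elements `mri`, `ct` (both `image_volume`) and `truth`
#'   (list: `labels` as a LABEL `image_volume`, `depot_masses_kg`,
#'   `label_codes`).
#' @export
generate_phantom <- function(spec, region = c("abdomen", "thigh")) {
  stopifnot(inherits(spec, "phantom_spec"))
  region <- match.arg(region)
  set.seed(spec$seed)

  px <- spec$pixel_size_mm
  margin_mm <- 12
  half <- ceiling((spec$body_radius_mm + margin_mm) / px)
  n <- 2L * half + 1L
  centre <- half + 1L
  coord <- (seq_len(n) - centre) * px
  xg <- matrix(coord, n, n)              # x varies along rows
  yg <- matrix(coord, n, n, byrow = TRUE)
  r <- sqrt(xg^2 + yg^2)
  theta <- atan2(yg, xg)

  thick <- if (is.function(spec$sat_thickness_mm))
    spec$sat_thickness_mm(theta) else spec$sat_thickness_mm
  r_inner <- spec$body_radius_mm - thick
  if (any(r_inner <= 0)) stop("SAT thickness exceeds body radius somewhere")

  organs <- spec$organ_layout
  if (is.null(organs)) {
    organs <- if (region == "abdomen") {
      list(list(label = "liver", center_mm = c(-35, 25), radii_mm = c(26, 18),
                slices = seq_len(max(1L, ceiling(spec$n_slices * 0.4)))))
    } else {
      list(list(label = "bone_marrow", center_mm = c(0, 0), radii_mm = c(12, 12),
                slices = seq_len(spec$n_slices)))
    }
  }

  labels <- array(PHANTOM_LABELS[["background"]],
                  c(n, n, spec$n_slices))
  base_slice <- matrix(PHANTOM_LABELS[["background"]], n, n)
  base_slice[r <= spec$body_radius_mm & r > r_inner] <- PHANTOM_LABELS[["sat"]]
  base_slice[r <= r_inner] <- PHANTOM_LABELS[["muscle"]]
  internal <- r <= r_inner

  for (z in seq_len(spec$n_slices)) {
    lab <- base_slice
    for (org in organs) {
      sl <- if (is.null(org$slices)) seq_len(spec$n_slices) else org$slices
      if (!(z %in% sl)) next
      e <- ((xg - org$center_mm[1]) / org$radii_mm[1])^2 +
           ((yg - org$center_mm[2]) / org$radii_mm[2])^2 <= 1
      lab[e & internal] <- PHANTOM_LABELS[[org$label]]
    }
    # scattered internal fat islands; target fraction of non-organ internal area
    eligible <- internal & lab == PHANTOM_LABELS[["muscle"]]
    target <- round(spec$internal_fat_fraction * sum(eligible))
    placed <- 0L
    tries <- 0L
    while (placed < target && tries < 500L) {
      tries <- tries + 1L
      blob_r <- stats::runif(1, 3, 7)                       # mm
      ang <- stats::runif(1, -pi, pi)
      rad <- sqrt(stats::runif(1)) * (max(0, min(r_inner) - blob_r - 2))
      cx <- rad * cos(ang); cy <- rad * sin(ang)
      blob <- (xg - cx)^2 + (yg - cy)^2 <= blob_r^2
      add <- blob & eligible
      if (!any(add)) next
      lab[add] <- PHANTOM_LABELS[["internal_fat"]]
      eligible <- eligible & !add
      placed <- placed + sum(add)
    }
    labels[, , z] <- lab
  }

  fat_codes <- PHANTOM_LABELS[c("sat", "internal_fat", "bone_marrow")]
  is_fat <- labels %in% fat_codes
  dim(is_fat) <- dim(labels)

  # --- MRI intensities ------------------------------------------------------
  mri_means <- c(`0` = 0, `1` = 1000, `2` = 400, `3` = 1000, `4` = 450,
                 `5` = 950)
  mri <- array(mri_means[as.character(labels)], dim(labels))

  if (spec$bias_amplitude > 0) {
    u <- xg / max(abs(coord)); v <- yg / max(abs(coord))
    for (z in seq_len(spec$n_slices)) {
      cf <- stats::rnorm(5)
      f <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
      f <- f / max(abs(f))
      mri[, , z] <- mri[, , z] * (1 + spec$bias_amplitude * f)
    }
  }
  if (spec$noise_sd > 0)
    mri <- mri + stats::rnorm(length(mri), sd = spec$noise_sd)

  # --- CT Hounsfield map ----------------------------------------------------
  ct <- array(-1000, dim(labels))
  ct[labels == PHANTOM_LABELS[["muscle"]]] <-
    pmax(-20, 40 + stats::rnorm(sum(labels == PHANTOM_LABELS[["muscle"]]), sd = 5))
  ct[labels == PHANTOM_LABELS[["liver"]]] <- 55
  ct[is_fat] <- stats::runif(sum(is_fat), -150, -50)

  spacing <- c(px, px, spec$slice_pitch_mm)
  vox_L <- prod(spacing) * 1e-6
  internal_name <- if (region == "abdomen") "visceral" else "inter_muscular"
  depots <- c(sat = PHANTOM_LABELS[["sat"]],
              internal_fat = PHANTOM_LABELS[["internal_fat"]],
              bone_marrow = PHANTOM_LABELS[["bone_marrow"]])
  names(depots)[2] <- internal_name
  masses <- vapply(depots, function(code)
    sum(labels == code) * vox_L * ADIPOSE_DENSITY_KG_PER_L, numeric(1))

  list(
    mri = image_volume(mri, spacing, modality = "MRI"),
    ct = image_volume(ct, spacing, modality = "CT"),
    truth = list(
      labels = image_volume(labels, spacing, modality = "LABEL"),
      depot_masses_kg = masses,
      label_codes = PHANTOM_LABELS,
      region = region
    )
  )
}
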