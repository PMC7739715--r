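#' Phantom specification
#'
#' Describes a synthetic axial T1-MRI / low-dose-CT phantom of an abdominal or
#' femoral cross-section: a circular body with a bright subcutaneous-fat (SAT)
#' annulus whose thickness may vary with angle, an internal muscle/organ
#' compartment with scattered visceral or inter-muscular fat, optional labeled
#' organs (liver, bone marrow) as ellipses, a smooth multiplicative bias field
#' and additive Gaussian noise.
#'
#' Default in-plane pixel size and slice pitch follow the acquisition geometry
#' of the study protocol this package emulates (1.1719 mm pixels, 6 mm slices
#' at 7.2 mm centre-to-centre pitch).
#'
#' @param n_slices number of axial slices.
#' @param pixel_size_mm in-plane pixel size (isotropic), mm.
#' @param slice_pitch_mm slice centre-to-centre spacing, mm.
#' @param body_radius_mm outer body radius, mm.
#' @param sat_thickness_mm SAT annulus thickness: a scalar, or a function of
#'   angle (radians) returning thickness in mm.
#' @param internal_fat_fraction target fraction of internal-compartment voxels
#'   occupied by scattered fat, in `[0, 1]`.
#' @param organ_layout list of organs, each a list with elements `label`
#'   (`"liver"` or `"bone_marrow"`), `center_mm` (length-2, relative to body
#'   centre), `radii_mm` (length-2 ellipse semi-axes) and optionally `slices`
#'   (slice indices; default all).
#' @param bias_amplitude peak-to-centre relative amplitude of the smooth
#'   multiplicative bias field (0 disables it).
#' @param noise_sd additive Gaussian noise standard deviation, in image
#'   intensity units (0 disables it).
#' @param seed integer seed; identical spec + seed reproduces the phantom
#'   bit for bit.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(n_slices = 10L,
                         pixel_size_mm = 1.1719,
                         slice_pitch_mm = 7.2,
                         body_radius_mm = 95,
                         sat_thickness_mm = 15,
                         internal_fat_fraction = 0.1,
                         organ_layout = NULL,
                         bias_amplitude = 0,
                         noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(n_slices) == 1L, n_slices >= 1)
  for (nm in c("pixel_size_mm", "slice_pitch_mm", "body_radius_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number")
  }
  if (!is.function(sat_thickness_mm)) {
    if (!is.numeric(sat_thickness_mm) || sat_thickness_mm <= 0 ||
        sat_thickness_mm >= body_radius_mm)
      stop("'sat_thickness_mm' must be positive and smaller than the body radius")
  }
  if (internal_fat_fraction < 0 || internal_fat_fraction > 1)
    stop("'internal_fat_fraction' must lie in [0, 1]")
  if (bias_amplitude < 0 || bias_amplitude > 1)
    stop("'bias_amplitude' must lie in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(
    list(n_slices = as.integer(n_slices), pixel_size_mm = pixel_size_mm,
         slice_pitch_mm = slice_pitch_mm, body_radius_mm = body_radius_mm,
         sat_thickness_mm = sat_thickness_mm,
         internal_fat_fraction = internal_fat_fraction,
         organ_layout = organ_layout, bias_amplitude = bias_amplitude,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# tissue label codes shared by the generator and the segmentation tests
PHANTOM_LABELS <- c(background = 0L, sat = 1L, muscle = 2L,
                    internal_fat = 3L, liver = 4L, bone_marrow = 5L)

#' Density used to convert adipose tissue volume to mass
#'
#' Adipose tissue density, 0.9 kg/L, applied whenever a depot volume is
#' converted to a mass.
#' @export
ADIPOSE_DENSITY_KG_PER_L <- 0.9
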