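#' Extract an image-derived input function from a dynamic PET series
#'
#' Averages each dynamic frame over an aorta VOI (typically a small cylinder
#' at the L2/L3 level) and timestamps the samples at the frame mid-times,
#' giving the blood FDG concentration curve without arterial sampling.
#'
#' @param dynamic list of PET `image_volume`s, one per frame.
#' @param aorta_voi logical/0-1 array, same grid as each frame.
#' @param schedule the `frame_schedule` of the series.
#' @return an `input_function` with `source = "IDIF"`.
#' @export
extract_idif <- function(dynamic, aorta_voi, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dynamic) != length(schedule$start_s))
    stop("number of frames does not match the schedule")
  voi <- aorta_voi > 0
  if (!any(voi)) stop("empty aorta VOI")
  means <- vapply(dynamic, function(fr) {
    v <- if (inherits(fr, "image_volume")) fr$voxels else fr
    mean(v[voi])
  }, numeric(1))
  input_function(frame_mid_times_min(schedule), pmax(means, 0), source = "IDIF")
}

#' Connected-threshold adipose VOI on CT
#'
#' Grows the 26-connected component of voxels with Hounsfield units in
#' `[-150, -50]` (inclusive at both ends) containing the seed point — the
#' standard CT definition of an adipose volume of interest. The seed itself
#' must measure adipose HU.
#'
#' @param ct a CT `image_volume`.
#' @param seed_point length-3 voxel index (1-based).
#' @param hu_range inclusive HU window.
#' @return logical array: the connected adipose component.
#' @export
segment_adipose_voi_ct <- function(ct, seed_point, hu_range = c(-150, -50)) {
  stopifnot(inherits(ct, "image_volume"))
  vox <- ct$voxels
  d <- dim(vox)
  sp <- as.integer(seed_point)
  if (any(sp < 1L) || any(sp > d)) stop("seed point outside the volume")
  hu <- vox[sp[1], sp[2], sp[3]]
  if (hu < hu_range[1] || hu > hu_range[2])
    stop(sprintf("seed HU %.1f outside adipose range [%g, %g]",
                 hu, hu_range[1], hu_range[2]))
  eligible <- vox >= hu_range[1] & vox <= hu_range[2]
  region <- array(FALSE, d)
  region[sp[1], sp[2], sp[3]] <- TRUE
  # vectorised 26-connected region growing: dilate within the eligible set
  repeat {
    grown <- region
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
      grown <- grown | region[xs, ys, zs]
    }
    grown <- grown & eligible
    if (identical(grown, region)) break
    region <- grown
  }
  region
}

#' Per-slice two-pixel erosion of a VOI
#'
#' Erodes each axial slice of a binary mask with a disc brush (radius 2
#' pixels by default), the spillover guard applied to all VOIs before
#' transfer onto the PET frames. The result is always contained in the input.
#'
#' @param mask logical/0-1 3-D array (or 2-D matrix).
#' @param pixels erosion radius in pixels.
#' @return logical array of the same shape.
#' @export
erode_voi <- function(mask, pixels = 2L) {
  was2d <- is.matrix(mask)
  arr <- if (was2d) array(mask > 0, c(dim(mask), 1L)) else mask > 0
  brush <- EBImage::makeBrush(2L * pixels + 1L, shape = "disc")
  out <- array(FALSE, dim(arr))
  for (z in seq_len(dim(arr)[3])) {
    sl <- arr[, , z]
    if (!any(sl)) next
    out[, , z] <- EBImage::erode(sl * 1, brush) > 0.5
  }
  if (was2d) out[, , 1] else out
}
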