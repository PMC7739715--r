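#' Unroll an axial slice into polar (angle x radius) coordinates
#'
#' Resamples a 2-D slice along rays from a centre point, so ring-shaped
#' structures (the subcutaneous fat annulus) become horizontal bands and
#' boundary detection reduces to finding one radius per angle. Sampling is
#' bilinear; the source coordinates of every polar sample are retained so
#' masks can be mapped back ("re-rolled") to the cartesian grid.
#'
#' @param slice2d numeric matrix (one axial slice).
#' @param center_px length-2 centre in (fractional) pixel coordinates.
#' @param n_angles number of angle columns over 2*pi.
#' @param radial_step_mm radial sampling step; defaults to half the in-plane
#'   pixel for sub-pixel boundary localisation.
#' @param spacing_mm in-plane pixel sizes (length 2 or scalar).
#' @param max_radius_mm outermost sampled radius; defaults to the largest
#'   radius fully inside the slice.
#' @return a `polar_image`: `samples` (n_angles x n_radii), `center_px`,
#'   `angular_step`, `radial_step_mm`, `spacing_mm`, `src_dim`, `inverse_map`.
#' @export
unroll_slice <- function(slice2d, center_px, n_angles = 360,
                         radial_step_mm = NULL, spacing_mm = c(1.1719, 1.1719),
                         max_radius_mm = NULL) {
  stopifnot(is.matrix(slice2d), length(center_px) == 2L)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  d <- dim(slice2d)
  if (center_px[1] < 1 || center_px[1] > d[1] ||
      center_px[2] < 1 || center_px[2] > d[2])
    stop("centre lies outside the slice")
  if (is.null(radial_step_mm)) radial_step_mm <- min(spacing_mm) / 2
  if (is.null(max_radius_mm)) {
    max_radius_mm <- min((center_px[1] - 1) * spacing_mm[1],
                         (d[1] - center_px[1]) * spacing_mm[1],
                         (center_px[2] - 1) * spacing_mm[2],
                         (d[2] - center_px[2]) * spacing_mm[2])
  }
  if (max_radius_mm <= radial_step_mm) stop("centre too close to the border")
  n_r <- floor(max_radius_mm / radial_step_mm) + 1L
  radii <- (seq_len(n_r) - 1) * radial_step_mm
  angles <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  # source pixel coordinates for every (angle, radius) sample
  px <- outer(cos(angles), radii) / spacing_mm[1] + center_px[1]
  py <- outer(sin(angles), radii) / spacing_mm[2] + center_px[2]
  samples <- bilinear_sample(slice2d, px, py)
  structure(
    list(samples = samples, center_px = center_px,
         angular_step = 2 * pi / n_angles, radial_step_mm = radial_step_mm,
         spacing_mm = spacing_mm, src_dim = d,
         inverse_map = list(px = px, py = py)),
    class = "polar_image"
  )
}

# vectorised bilinear interpolation; outside-grid samples return 0
bilinear_sample <- function(img, px, py) {
  d <- dim(img)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  x0c <- pmin(pmax(x0, 1L), d[1]); x1c <- pmin(x0c + 1L, d[1])
  y0c <- pmin(pmax(y0, 1L), d[2]); y1c <- pmin(y0c + 1L, d[2])
  v <- (1 - fx) * (1 - fy) * img[cbind(c(x0c), c(y0c))] +
       fx * (1 - fy) * img[cbind(c(x1c), c(y0c))] +
       (1 - fx) * fy * img[cbind(c(x0c), c(y1c))] +
       fx * fy * img[cbind(c(x1c), c(y1c))]
  out <- ifelse(px >= 1 & px <= d[1] & py >= 1 & py <= d[2], v, 0)
  dim(out) <- dim(px)
  out
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d angles x %d radii, step %.3f mm\n",
              nrow(x$samples), ncol(x$samples), x$radial_step_mm))
  invisible(x)
}
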