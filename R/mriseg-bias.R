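#' Estimate a per-slice foreground mask ("body mask")
#'
#' Separates tissue from air per axial slice: a global two-class k-means
#' threshold on the slice intensities, then the largest connected foreground
#' component with interior holes filled. Slices with no foreground yield an
#' empty mask with a warning (not an error) so partially empty volumes pass
#' through.
#'
#' @param volume an MRI `image_volume`.
#' @return a LABEL `image_volume` holding a 0/1 mask.
#' @export
body_mask <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  if (volume$modality != "MRI") stop("body_mask expects an MRI volume")
  vox <- volume$voxels
  out <- array(0L, dim(vox))
  for (z in seq_len(dim(vox)[3])) {
    sl <- vox[, , z]
    if (stats::sd(sl) < 1e-9) {
      warning("slice ", z, " has no contrast; empty body mask")
      next
    }
    km <- stats::kmeans(as.vector(sl), centers = range(sl), iter.max = 50)
    thr <- mean(km$centers)
    fg <- sl > thr
    if (!any(fg)) {
      warning("slice ", z, " is all background; empty body mask")
      next
    }
    lab <- EBImage::bwlabel(fg)
    tab <- tabulate(lab[lab > 0])
    keep <- lab == which.max(tab)
    keep <- EBImage::fillHull(keep)
    out[, , z] <- as.integer(keep > 0)
  }
  image_volume(out, volume$spacing_mm, volume$origin_mm, modality = "LABEL")
}

#' Correct a smooth multiplicative intensity bias field
#'
#' Per-slice homomorphic correction: the log-intensity inside the foreground
#' is modelled as a low-order 2-D polynomial bias plus per-tissue-class
#' offsets, estimated by alternating k-means tissue classification and
#' least-squares polynomial fitting. The fitted field (degree 4 by default)
#' is divided out and the slice rescaled so the mean foreground intensity is
#' preserved. A bias-free image passes through essentially unchanged.
#'
#' @param volume an MRI `image_volume`.
#' @param degree total polynomial degree of the field model.
#' @param foreground optional 0/1 LABEL `image_volume`; computed with
#'   [body_mask()] when missing.
#' @param n_classes tissue classes used while estimating the field.
#' @param n_iter alternating iterations.
#' @return the corrected `image_volume`.
#' @export
correct_bias <- function(volume, degree = 4, foreground = NULL,
                         n_classes = 2, n_iter = 4) {
  stopifnot(inherits(volume, "image_volume"))
  if (volume$modality != "MRI") stop("correct_bias expects an MRI volume")
  if (is.null(foreground)) foreground <- body_mask(volume)
  fg_arr <- foreground$voxels > 0
  if (!any(fg_arr)) stop("empty foreground: nothing to correct")

  vox <- volume$voxels
  out <- vox
  d <- dim(vox)
  xi <- matrix(seq_len(d[1]), d[1], d[2])
  yi <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)

  for (z in seq_len(d[3])) {
    fg <- fg_arr[, , z]
    if (!any(fg)) next
    sl <- vox[, , z]
    L <- log(pmax(sl, 1e-6))
    u <- (xi[fg] - mean(xi[fg])) / max(1, stats::sd(xi[fg]))
    v <- (yi[fg] - mean(yi[fg])) / max(1, stats::sd(yi[fg]))
    X <- poly2d_basis(u, v, degree)
    Lf <- L[fg]
    if (stats::sd(Lf) < 1e-9) next        # constant slice: nothing to do
    field <- rep(0, length(Lf))
    for (it in seq_len(n_iter)) {
      z0 <- Lf - field
      if (length(unique(round(z0, 9))) < n_classes) break
      km <- suppressWarnings(
        stats::kmeans(z0, centers = stats::quantile(z0, seq(0.1, 0.9,
                      length.out = n_classes)), iter.max = 50))
      centred <- Lf - km$centers[km$cluster]
      fit <- stats::lm.fit(X, centred)
      field <- fit$fitted.values
      field <- field - mean(field)
    }
    corr <- sl
    corr[fg] <- exp(Lf - field)
    corr[fg] <- corr[fg] * (mean(sl[fg]) / mean(corr[fg]))
    out[, , z] <- corr
  }
  image_volume(out, volume$spacing_mm, volume$origin_mm, modality = "MRI")
}

poly2d_basis <- function(u, v, degree) {
  cols <- list(rep(1, length(u)))
  for (total in seq_len(degree))
    for (i in 0:total)
      cols[[length(cols) + 1L]] <- u^(total - i) * v^i
  do.call(cbind, cols)
}
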