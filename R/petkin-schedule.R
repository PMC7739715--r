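#' Dynamic PET frame schedule
#'
#' Builds a contiguous frame schedule from a `(count, duration)` pattern, the
#' way dynamic acquisitions are histogrammed. The study protocol this package
#' follows used 26 frames over 60 min: 12 x 10 s, 4 x 120 s, 10 x 300 s.
#'
#' @param pattern list of `c(count, duration_s)` pairs (or a 2-column matrix).
#' @return A `frame_schedule` with per-frame `start_s` and `duration_s`.
#' @export
build_frame_schedule <- function(pattern = list(c(12, 10), c(4, 120), c(10, 300))) {
  if (is.matrix(pattern)) pattern <- asplit(pattern, 1)
  if (length(pattern) == 0L) stop("empty frame pattern")
  durations <- unlist(lapply(pattern, function(p) {
    if (length(p) != 2L || any(p <= 0))
      stop("each pattern entry must be a positive (count, duration_s) pair")
    rep(p[2], p[1])
  }))
  start_s <- cumsum(c(0, durations[-length(durations)]))
  structure(list(start_s = start_s, duration_s = durations),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, 0 - %.0f s (%.1f min)\n",
              length(x$start_s), sum(x$duration_s), sum(x$duration_s) / 60))
  invisible(x)
}

#' Frame mid-times in minutes
#' @param schedule a `frame_schedule`.
#' @return numeric vector of frame midpoints, minutes.
#' @export
frame_mid_times_min <- function(schedule) {
  (schedule$start_s + schedule$duration_s / 2) / 60
}

#' Time-activity curve
#'
#' Per-frame mean VOI activity on a frame schedule. `decay_corrected_to`
#' records the correction state: `"scan_start"` (the usual delivery state of
#' reconstructed data) or `"none"` (physical, decaying activity).
#'
#' @param schedule a `frame_schedule`.
#' @param activity_kBq_per_ml per-frame mean activity, non-negative.
#' @param decay_corrected_to correction reference.
#' @return a `tac` object.
#' @export
tac <- function(schedule, activity_kBq_per_ml,
                decay_corrected_to = c("scan_start", "none")) {
  decay_corrected_to <- match.arg(decay_corrected_to)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(activity_kBq_per_ml) != length(schedule$start_s))
    stop("activity length must match the number of frames")
  if (any(activity_kBq_per_ml < 0)) stop("activities must be non-negative")
  structure(list(schedule = schedule,
                 activity_kBq_per_ml = as.numeric(activity_kBq_per_ml),
                 decay_corrected_to = decay_corrected_to),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, peak %.2f kBq/mL, decay-corrected to %s\n",
              length(x$activity_kBq_per_ml), max(x$activity_kBq_per_ml),
              x$decay_corrected_to))
  invisible(x)
}

#' F-18 half-life in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Apply or remove decay correction on a time-activity curve
#'
#' Per-frame factor `exp(lambda * t_mid)` with `lambda = ln 2 / half-life`
#' and `t_mid` the frame midpoint, referenced to scan start. Applying to an
#' already-corrected curve (or removing twice) is refused via the
#' `decay_corrected_to` flag; apply-then-remove is an identity.
#'
#' @param x a `tac`.
#' @param half_life_min isotope half-life (default F-18, 109.77 min).
#' @param direction `"apply"` (physical -> corrected) or `"remove"`.
#' @return a `tac` with updated activities and correction flag.
#' @export
decay_correct <- function(x, half_life_min = F18_HALF_LIFE_MIN,
                          direction = c("apply", "remove")) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "tac"))
  if (direction == "apply" && x$decay_corrected_to != "none")
    stop("curve is already decay-corrected to ", x$decay_corrected_to)
  if (direction == "remove" && x$decay_corrected_to == "none")
    stop("curve carries no decay correction to remove")
  lambda <- log(2) / half_life_min
  factor <- exp(lambda * frame_mid_times_min(x$schedule))
  if (direction == "apply") {
    tac(x$schedule, x$activity_kBq_per_ml * factor, "scan_start")
  } else {
    tac(x$schedule, x$activity_kBq_per_ml / factor, "none")
  }
}
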