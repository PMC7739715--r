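#' Read and write time-activity curves as CSV
#'
#' Columns `start_s`, `duration_s`, `activity_kBq_per_ml`; the decay
#' correction state travels in a `decay_corrected_to` column (constant).
#'
#' @param x a `tac`.
#' @param path CSV path.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(
    data.frame(start_s = x$schedule$start_s,
               duration_s = x$schedule$duration_s,
               activity_kBq_per_ml = x$activity_kBq_per_ml,
               decay_corrected_to = x$decay_corrected_to),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path)
  sched <- structure(list(start_s = df$start_s, duration_s = df$duration_s),
                     class = "frame_schedule")
  tac(sched, df$activity_kBq_per_ml,
      decay_corrected_to = as.character(df$decay_corrected_to[1]))
}

#' Read and write cohort tables as CSV
#' @param table a cohort data.frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = unique(df$group))
  df$time <- factor(df$time, levels = unique(df$time))
  df
}

#' Dice overlap of two binary masks
#' @param a,b logical/0-1 arrays of identical shape.
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty).
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
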