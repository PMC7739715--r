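#' Kinetic parameters of the irreversible two-tissue-compartment FDG model
#'
#' `K1` (mL blood per mL tissue per min) carries tracer into the free
#' compartment, `k2` (1/min) back out, `k3` (1/min) into the trapped
#' (phosphorylated) pool; `k4` is fixed at 0 (irreversible). `Vb` is the
#' fractional blood volume. The net influx rate constant is
#' `Ki = K1 k3 / (k2 + k3)`, which never exceeds `K1`.
#'
#' @param K1,k2,k3 non-negative rate constants.
#' @param Vb blood volume fraction in `[0, 1]`.
#' @return a `kinetic_params` object with derived field `ki`.
#' @export
kinetic_params <- function(K1, k2, k3, Vb = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, Vb = Vb)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rate constants and Vb must be non-negative and finite")
  if (Vb > 1) stop("Vb is a fraction and cannot exceed 1")
  ki <- if (k2 + k3 == 0) K1 else K1 * k3 / (k2 + k3)
  structure(list(K1 = K1, k2 = k2, k3 = k3, Vb = Vb, ki = ki),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> K1=%.4g k2=%.4g k3=%.4g Vb=%.3g  Ki=%.5g mL/mL/min\n",
              x$K1, x$k2, x$k3, x$Vb, x$ki))
  invisible(x)
}

#' Tissue concentration of the irreversible 2TCM on a fine grid
#'
#' Evaluates
#' `Ct(t) = Vb Cp(t) + K1/(k2+k3) * [k3 + k2 e^(-(k2+k3)t)] (x) Cp(t)`
#' (`(x)` = convolution, `k4 = 0`) by discrete convolution on a uniform grid.
#'
#' @param input an `input_function`.
#' @param params a [kinetic_params()].
#' @param t_max_min end of the grid, minutes.
#' @param dt_min grid step, minutes.
#' @return list with `t` (minutes) and `ct` (kBq/mL).
#' @export
tissue_curve_2tcm <- function(input, params, t_max_min, dt_min = 0.01) {
  stopifnot(inherits(params, "kinetic_params"))
  t <- seq(0, t_max_min, by = dt_min)
  cp <- input_function_at(input, t)
  kb <- params$k2 + params$k3
  h <- if (kb == 0) rep(params$K1, length(t))
       else params$K1 / kb * (params$k3 + params$k2 * exp(-kb * t))
  full <- stats::convolve(cp, rev(h), type = "open")[seq_along(t)]
  conv <- (full - 0.5 * (h[1] * cp + h * cp[1])) * dt_min   # trapezoid ends
  list(t = t, ct = params$Vb * cp + conv)
}

#' Simulate a frame-averaged tissue time-activity curve
#'
#' Forward-simulates the irreversible two-tissue model over a frame schedule:
#' the continuous tissue curve is integrated within each frame and divided by
#' the frame duration, matching what a reconstructed dynamic series reports.
#' Optional multiplicative Gaussian noise (`sd = noise_sd * frame value`)
#' emulates count-limited frames; `noise_sd = 0` is exactly deterministic.
#'
#' @param input an `input_function`.
#' @param params a [kinetic_params()].
#' @param schedule a `frame_schedule`.
#' @param noise_sd relative noise level (fraction of each frame's value).
#' @param seed integer seed used when `noise_sd > 0`.
#' @param dt_min integration step, minutes.
#' @return a `tac` (decay-corrected-to-scan-start convention, as simulated
#'   activity concentrations).
#' @export
simulate_tissue_tac <- function(input, params, schedule, noise_sd = 0,
                                seed = 1L, dt_min = 0.01) {
  stopifnot(inherits(schedule, "frame_schedule"))
  t_end_min <- sum(schedule$duration_s) / 60
  fine <- tissue_curve_2tcm(input, params, t_end_min, dt_min)
  start_min <- schedule$start_s / 60
  end_min <- (schedule$start_s + schedule$duration_s) / 60
  act <- vapply(seq_along(start_min), function(i) {
    sel <- fine$t >= start_min[i] & fine$t <= end_min[i]
    mean(fine$ct[sel])
  }, numeric(1))
  if (noise_sd > 0) {
    set.seed(seed)
    act <- act * (1 + stats::rnorm(length(act), sd = noise_sd))
  }
  tac(schedule, pmax(act, 0), "scan_start")
}

#' Closed-form 2TCM tissue curve for a constant input
#'
#' For `Cp(t) = c` the convolution integrates analytically to
#' `Ct(t) = Vb c + c K1/(k2+k3) [k3 t + k2/(k2+k3) (1 - e^(-(k2+k3)t))]`;
#' used as an independent oracle for the numerical simulator.
#'
#' @param params a [kinetic_params()].
#' @param cp_const constant plasma concentration.
#' @param t_min times in minutes.
#' @return tissue concentrations.
#' @export
tissue_curve_2tcm_constant_cp <- function(params, cp_const, t_min) {
  kb <- params$k2 + params$k3
  if (kb == 0) return(params$Vb * cp_const + params$K1 * cp_const * t_min)
  params$Vb * cp_const + cp_const * params$K1 / kb *
    (params$k3 * t_min + params$k2 / kb * (1 - exp(-kb * t_min)))
}
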