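#' Patlak graphical analysis of an irreversible tracer
#'
#' Plots `y = Ct(t)/Cp(t)` against the normalised time
#' `x = int_0^t Cp / Cp(t)` at the frame mid-times and fits ordinary least
#' squares to the points with mid-time at or beyond `t_star_min`. For an
#' irreversible tracer the late-time slope is the net influx rate constant
#' `Ki = K1 k3 / (k2 + k3)` and the intercept the initial distribution
#' volume. The cumulative plasma integral is taken by trapezoid over the
#' sampled input function (a leading zero sample is assumed when the curve
#' does not start at t = 0).
#'
#' @param x a `tac`.
#' @param input an `input_function`.
#' @param t_star_min start of the linear regime, minutes (default 20).
#' @return a `patlak_fit`: `ki`, `intercept_V0`, `r_squared`, `t_star_min`,
#'   `n_points`.
#' @export
patlak_ki <- function(x, input, t_star_min = 20) {
  stopifnot(inherits(x, "tac"), inherits(input, "input_function"))
  tm <- frame_mid_times_min(x$schedule)
  tt <- input$times_min
  cc <- input$cp_kBq_per_ml
  if (tt[1] > 0) { tt <- c(0, tt); cc <- c(0, cc) }
  cum_cp <- pracma::cumtrapz(tt, cc)[, 1]
  int_cp <- stats::approx(tt, cum_cp, xout = tm, rule = 2)$y
  cp_mid <- input_function_at(input, tm)
  sel <- tm >= t_star_min
  if (sum(sel) < 3) stop("need at least 3 frames at or beyond t* = ",
                         t_star_min, " min")
  if (any(cp_mid[sel] <= 0)) stop("plasma concentration is zero beyond t*")
  px <- int_cp[sel] / cp_mid[sel]
  py <- x$activity_kBq_per_ml[sel] / cp_mid[sel]
  fit <- stats::lm(py ~ px)
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn harmlessly
  structure(list(ki = unname(stats::coef(fit)[2]),
                 intercept_V0 = unname(stats::coef(fit)[1]),
                 r_squared = if (is.nan(r2)) 1 else r2,
                 t_star_min = t_star_min, n_points = sum(sel)),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> Ki = %.5g mL/mL/min, V0 = %.4g, R2 = %.4f (%d points, t* = %g min)\n",
              x$ki, x$intercept_V0, x$r_squared, x$n_points, x$t_star_min))
  invisible(x)
}

# fast frame-averaged forward model of the irreversible 2TCM on a fine grid;
# the exponential convolution is a recursive (O(n)) trapezoid filter
make_2tcm_forward <- function(input, schedule, dt_min = 0.01) {
  t_end <- sum(schedule$duration_s) / 60
  t <- seq(0, t_end, by = dt_min)
  cp <- input_function_at(input, t)
  cum_cp <- c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2 * dt_min))
  i0 <- pmax(1L, round(schedule$start_s / 60 / dt_min) + 1L)
  i1 <- pmin(length(t), round((schedule$start_s + schedule$duration_s) / 60 / dt_min) + 1L)
  function(K1, k2, k3, Vb) {
    beta <- k2 + k3
    conv <- if (beta < 1e-12) {
      K1 * cum_cp
    } else {
      decay <- exp(-beta * dt_min)
      inc <- dt_min / 2 * (cp[-1] + decay * cp[-length(cp)])
      e_conv <- c(0, stats::filter(inc, decay, method = "recursive"))
      K1 * k3 / beta * cum_cp + K1 * k2 / beta * e_conv
    }
    ct <- Vb * cp + conv
    cum_ct <- c(0, cumsum((ct[-1] + ct[-length(ct)]) / 2 * dt_min))
    (cum_ct[i1] - cum_ct[i0]) / (t[i1] - t[i0])
  }
}

#' Fit the irreversible two-tissue-compartment model to a dynamic TAC
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt with box
#' constraints, frames weighted by duration) for `K1`, `k2`, `k3` and `Vb`
#' with `k4` fixed at 0, run from several seeded starting points to reduce
#' the risk of a local minimum. Non-convergence of every start is flagged in
#' the result rather than silently ignored.
#'
#' @param x a `tac`.
#' @param input an `input_function`.
#' @param init optional [kinetic_params()] starting values.
#' @param seed seed for the multi-start jitter.
#' @param n_starts number of starting points.
#' @param dt_min forward-model grid step, minutes.
#' @return a [kinetic_params()] with attributes `residual_norm`,
#'   `converged`, `n_starts`.
#' @export
fit_2tcm_irreversible <- function(x, input, init = NULL, seed = 1L,
                                  n_starts = 4L, dt_min = 0.01) {
  stopifnot(inherits(x, "tac"))
  if (is.null(init)) init <- kinetic_params(0.05, 0.3, 0.05, Vb = 0.03)
  if (any(c(init$K1, init$k2, init$k3) <= 0))
    stop("initial rate constants must be positive")
  fwd <- make_2tcm_forward(input, x$schedule, dt_min)
  obs <- x$activity_kBq_per_ml
  w <- sqrt(x$schedule$duration_s / mean(x$schedule$duration_s))
  resid_fn <- function(p) w * (fwd(p[1], p[2], p[3], p[4]) - obs)

  set.seed(seed)
  starts <- rbind(
    c(init$K1, init$k2, init$k3, init$Vb),
    matrix(abs(c(init$K1, init$k2, init$k3, pmax(init$Vb, 0.02)) *
               exp(stats::rnorm(4 * (n_starts - 1), 0, 0.5))),
           ncol = 4, byrow = TRUE)
  )
  starts[, 4] <- pmin(starts[, 4], 0.5)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = c(1e-6, 1e-6, 0, 0), upper = c(2, 10, 2, 1),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    any_conv <- any_conv || conv
    ssq <- sum(fit$fvec^2)
    if (is.null(best) || ssq < best$ssq)
      best <- list(par = fit$par, ssq = ssq, converged = conv)
  }
  if (is.null(best)) stop("2TCM fit failed from every starting point")
  if (!any_conv) warning("2TCM fit did not formally converge; returning best point found")
  out <- kinetic_params(best$par[1], best$par[2], best$par[3], best$par[4])
  attr(out, "residual_norm") <- sqrt(best$ssq)
  attr(out, "converged") <- any_conv
  attr(out, "n_starts") <- nrow(starts)
  out
}

#' Extrapolated IDIF area under the curve
#'
#' Trapezoid AUC over the sampled range plus an analytic tail from a
#' mono-exponential fitted to the final `tail_window_min` minutes,
#' integrated to `to_time_min` — how the blood exposure is carried from the
#' end of the dynamic scan (60 min) to the middle of the later static frames
#' (70 min). A non-decaying tail falls back to constant extrapolation with a
#' warning.
#'
#' @param input an `input_function` covering at least 30 min.
#' @param to_time_min extrapolation target time (default 70).
#' @param tail_window_min window used for the tail fit.
#' @return AUC in kBq.min/mL.
#' @export
extrapolate_idif_auc <- function(input, to_time_min = 70,
                                 tail_window_min = 20) {
  stopifnot(inherits(input, "input_function"))
  tt <- input$times_min
  cc <- input$cp_kBq_per_ml
  if (max(tt) < 30) stop("input function must cover at least 30 min")
  if (to_time_min < max(tt)) stop("'to_time_min' precedes the last sample")
  if (tt[1] > 0) { tt <- c(0, tt); cc <- c(0, cc) }
  auc <- pracma::trapz(tt, cc)
  if (to_time_min == max(tt)) return(auc)

  t_end <- max(tt)
  sel <- tt >= t_end - tail_window_min & cc > 0
  lam <- NA_real_
  if (sum(sel) >= 3) {
    fit <- stats::lm(log(cc[sel]) ~ tt[sel])
    lam <- -unname(stats::coef(fit)[2])
  }
  c_end <- cc[length(cc)]
  if (!is.finite(lam) || lam <= 0) {
    warning("input-function tail is not decaying; constant extrapolation used")
    return(auc + c_end * (to_time_min - t_end))
  }
  auc + c_end / lam * (1 - exp(-lam * (to_time_min - t_end)))
}

#' Estimated Ki from a static acquisition (fractional uptake rate)
#'
#' The mean VOI activity of the static frame divided by the time-integrated
#' blood concentration (the extrapolated IDIF AUC). For an irreversible
#' tracer this fractional uptake rate upper-bounds the Patlak Ki, the gap
#' shrinking as the static mid-time grows.
#'
#' @param mean_voi_activity mean static-frame VOI activity, kBq/mL.
#' @param auc extrapolated blood AUC, kBq.min/mL (> 0).
#' @param mid_time_min mid-time of the static frame (default 70 min).
#' @return a `static_uptake`: `estimated_ki`, components echoed.
#' @export
estimated_ki_static <- function(mean_voi_activity, auc, mid_time_min = 70) {
  if (auc <= 0) stop("blood AUC must be positive")
  if (mean_voi_activity < 0) stop("activity must be non-negative")
  structure(list(mean_voi_activity_kBq_per_ml = mean_voi_activity,
                 mid_time_min = mid_time_min, auc_kBq_min_per_ml = auc,
                 estimated_ki = mean_voi_activity / auc),
            class = "static_uptake")
}

#' Metabolic rate of glucose from an FDG influx rate constant
#'
#' `MRglucose = 1000 * Ki * [glucose] / (LC * density)` in
#' umol per kg tissue per minute: the influx constant (mL blood/mL
#' tissue/min) times the plasma glucose concentration (mmol/L), scaled by
#' the lumped constant (1.14 for adipose tissue) that converts FDG to
#' glucose flux and by the tissue density (0.9 g/mL) that converts per-mL to
#' per-kg.
#'
#' @param ki influx rate constant, mL/mL/min.
#' @param plasma_glucose_mmol_per_L plasma glucose during the clamp.
#' @param lumped_constant adipose lumped constant.
#' @param density_g_per_ml adipose density.
#' @return an `mr_glucose_result` with field `mr_glucose`
#'   (umol.kg^-1.min^-1).
#' @export
mr_glucose <- function(ki, plasma_glucose_mmol_per_L, lumped_constant = 1.14,
                       density_g_per_ml = 0.9) {
  vals <- c(ki, plasma_glucose_mmol_per_L, lumped_constant, density_g_per_ml)
  if (any(!is.finite(vals)) || any(vals < 0) || lumped_constant == 0 ||
      density_g_per_ml == 0)
    stop("inputs must be non-negative (LC and density positive)")
  structure(list(ki_used = ki,
                 plasma_glucose_mmol_per_L = plasma_glucose_mmol_per_L,
                 lumped_constant = lumped_constant,
                 density_g_per_ml = density_g_per_ml,
                 mr_glucose = 1000 * ki * plasma_glucose_mmol_per_L /
                   (lumped_constant * density_g_per_ml)),
            class = "mr_glucose_result")
}

#' @export
print.mr_glucose_result <- function(x, ...) {
  cat(sprintf("<mr_glucose> %.3f umol/kg/min (Ki = %.5g, glucose = %.2f mM, LC = %.2f, rho = %.2f)\n",
              x$mr_glucose, x$ki_used, x$plasma_glucose_mmol_per_L,
              x$lumped_constant, x$density_g_per_ml))
  invisible(x)
}
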