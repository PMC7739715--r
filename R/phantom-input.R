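#' Simulate an arterial/image-derived input function
#'
#' Generates a plasma FDG concentration curve of the Feng type: a sharp early
#' peak followed by bi-exponential washout,
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'       + A_3 e^{-\lambda_3 t},}
#' the standard analytic stand-in for a measured input function. A constant
#' plasma mode (`family = "constant"`) is available for closed-form checks.
#'
#' @param model_params for `family = "feng"` a list with `A` (length-3,
#'   kBq/mL/min for `A[1]`, kBq/mL for the rest) and `lambda` (length-3,
#'   1/min, decreasing); for `family = "constant"` a list with `value`.
#' @param times_min sampling times in minutes, non-negative and increasing.
#' @param family curve family.
#' @return An `input_function` with fields `times_min`, `cp_kBq_per_ml`,
#'   `source`, `family`, `params`.
#' @export
simulate_input_function <- function(model_params = feng_default_params(),
                                    times_min,
                                    family = c("feng", "constant")) {
  family <- match.arg(family)
  times_min <- as.numeric(times_min)
  if (any(times_min < 0)) stop("times must be non-negative")
  if (is.unsorted(times_min, strictly = TRUE))
    stop("times must be strictly increasing")
  cp <- eval_input_model(model_params, times_min, family)
  if (any(cp < -1e-9)) stop("input model produced negative concentrations")
  structure(
    list(times_min = times_min, cp_kBq_per_ml = pmax(cp, 0),
         source = "simulated", family = family, params = model_params),
    class = "input_function"
  )
}

#' Default Feng input-function parameters
#'
#' Conventional FDG bolus parameters (peak within the first minute, slow
#' terminal washout), scaled to peak near 100 kBq/mL.
#' @export
feng_default_params <- function() {
  list(A = c(851.1, 21.9, 20.8) * 0.12, lambda = c(4.134, 0.1191, 0.0104))
}

eval_input_model <- function(params, t, family) {
  if (family == "constant") return(rep(params$value, length(t)))
  A <- params$A; lam <- params$lambda
  (A[1] * t - A[2] - A[3]) * exp(-lam[1] * t) +
    A[2] * exp(-lam[2] * t) + A[3] * exp(-lam[3] * t)
}

#' Evaluate an input function at arbitrary times
#'
#' Analytic evaluation for model-backed curves; linear interpolation (constant
#' beyond the last sample) for sampled ones.
#' @param input an `input_function`.
#' @param t_min times in minutes.
#' @return concentrations in kBq/mL.
#' @export
input_function_at <- function(input, t_min) {
  stopifnot(inherits(input, "input_function"))
  if (!is.null(input$family) && !is.null(input$params)) {
    pmax(eval_input_model(input$params, pmax(t_min, 0), input$family), 0)
  } else {
    stats::approx(input$times_min, input$cp_kBq_per_ml, xout = t_min,
                  rule = 2)$y
  }
}

#' Analytic area under an input function
#'
#' Closed-form integral from 0 to `to_min` for model-backed curves
#' (term-by-term exponential integrals); trapezoid on the samples otherwise.
#'
#' @param input an `input_function`.
#' @param to_min upper limit in minutes.
#' @return AUC in kBq.min/mL.
#' @export
input_function_auc <- function(input, to_min) {
  stopifnot(inherits(input, "input_function"), to_min >= 0)
  if (is.null(input$family) || is.null(input$params)) {
    keep <- input$times_min <= to_min
    return(pracma::trapz(input$times_min[keep], input$cp_kBq_per_ml[keep]))
  }
  if (input$family == "constant") return(input$params$value * to_min)
  A <- input$params$A; lam <- input$params$lambda
  int_exp <- function(a, l, T) if (l == 0) a * T else a / l * (1 - exp(-l * T))
  int_texp <- function(a, l, T) {
    if (l == 0) return(a * T^2 / 2)
    a / l^2 * (1 - exp(-l * T) * (1 + l * T))
  }
  int_texp(A[1], lam[1], to_min) - int_exp(A[2] + A[3], lam[1], to_min) +
    int_exp(A[2], lam[2], to_min) + int_exp(A[3], lam[3], to_min)
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %s (%s), %d samples over [%.1f, %.1f] min, peak %.2f kBq/mL\n",
              x$source, if (is.null(x$family)) "sampled" else x$family,
              length(x$times_min), min(x$times_min), max(x$times_min),
              max(x$cp_kBq_per_ml)))
  invisible(x)
}

#' Construct an input function from samples
#'
#' @param times_min sampling times (minutes, increasing).
#' @param cp_kBq_per_ml non-negative concentrations.
#' @param source provenance tag (`"IDIF"` or `"simulated"`).
#' @return an `input_function` without an analytic backing model.
#' @export
input_function <- function(times_min, cp_kBq_per_ml, source = "IDIF") {
  times_min <- as.numeric(times_min)
  if (is.unsorted(times_min, strictly = TRUE)) stop("times must be increasing")
  if (any(cp_kBq_per_ml < 0)) stop("concentrations must be non-negative")
  structure(list(times_min = times_min,
                 cp_kBq_per_ml = as.numeric(cp_kBq_per_ml),
                 source = source, family = NULL, params = NULL),
            class = "input_function")
}
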