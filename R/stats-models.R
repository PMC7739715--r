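#' Mixed model with group, time and participant as repeated measure
#'
#' Fits `value ~ group * time` with a random intercept per participant
#' (compound symmetry) by REML, the standard repeated-measures analysis for a
#' two-group, two-time intervention. Tests use containment (within-subject)
#' denominator degrees of freedom, which are deterministic and exact for a
#' balanced two-period design; with balanced complete data the time contrast
#' reproduces the paired t-test. Within-group change contrasts are computed
#' by ls-means (unadjusted, as is conventional for this design).
#'
#' If the random-intercept fit is singular or fails (for instance with zero
#' within-subject variance), the model falls back to a paired analysis with a
#' warning.
#'
#' @param table a cohort data.frame (see [simulate_cohort()]): columns
#'   `participant_id`, `group`, `time`, `outcome`, `value`.
#' @param outcome which outcome to analyse.
#' @param log_scale analyse `log(value)` instead of raw values.
#' @return an `effect_report`: data.frame `terms` (estimate, SE, statistic,
#'   df, p per fixed term), data.frame `within_group` (ls-means change within
#'   each group), `model = "mixed"`, `note` on adjustment policy.
#' @export
mixed_model_group_time <- function(table, outcome, log_scale = FALSE) {
  dat <- prepare_cohort(table, outcome, log_scale)
  if (nlevels(droplevels(dat$group)) < 2)
    stop("need both groups present")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- tryCatch(
    nlme::lme(value ~ group * time, random = ~ 1 | participant_id,
              data = dat, method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed model failed to fit; falling back to paired analysis")
    return(paired_fallback(dat))
  }
  tt <- summary(fit)$tTable
  an <- stats::anova(fit, type = "marginal")
  terms_df <- data.frame(
    term = c("group", "time", "group:time"),
    statistic = an[c("group", "time", "group:time"), "F-value"],
    df_num = an[c("group", "time", "group:time"), "numDF"],
    df_den = an[c("group", "time", "group:time"), "denDF"],
    p_value = an[c("group", "time", "group:time"), "p-value"],
    row.names = NULL)
  # estimates/SEs from the coefficient table (treatment coding)
  est <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                    se = tt[, "Std.Error"], row.names = NULL)
  emm <- emmeans::emmeans(fit, ~ time | group, data = dat)
  wg <- as.data.frame(emmeans::contrast(emm, method = "revpairwise",
                                        adjust = "none"))
  effect_report(terms_df, est, wg, model = "mixed",
                note = "ls-means within-group contrasts unadjusted")
}

prepare_cohort <- function(table, outcome, log_scale) {
  stopifnot(all(c("participant_id", "group", "time", "outcome", "value")
                %in% names(table)))
  dat <- table[table$outcome == outcome, , drop = FALSE]
  if (!nrow(dat)) stop("outcome '", outcome, "' not present in the table")
  dup <- duplicated(dat[, c("participant_id", "time")])
  if (any(dup)) stop("more than one value per participant x time")
  one_group <- tapply(as.character(dat$group), dat$participant_id,
                      function(g) length(unique(g)))
  if (any(one_group > 1)) stop("a participant appears in both groups")
  dat$group <- factor(dat$group)
  dat$time <- factor(dat$time)
  if (log_scale) dat$value <- log(dat$value)
  dat
}

# analysis of subject differences, used when the random-intercept fit is
# degenerate (e.g. zero within-subject variance); deterministic and exact
paired_fallback <- function(dat) {
  wide <- stats::reshape(dat[, c("participant_id", "group", "time", "value")],
                         idvar = c("participant_id", "group"),
                         timevar = "time", direction = "wide")
  d <- wide[[paste0("value.", levels(dat$time)[2])]] -
       wide[[paste0("value.", levels(dat$time)[1])]]
  g <- droplevels(wide$group)
  means <- tapply(d, g, mean)
  sds <- tapply(d, g, stats::sd)
  ns <- tapply(d, g, length)
  wg <- data.frame(group = names(means),
                   contrast = paste(levels(dat$time)[2], "-", levels(dat$time)[1]),
                   estimate = as.numeric(means),
                   SE = as.numeric(sds / sqrt(ns)))
  wg$t.ratio <- ifelse(wg$SE > 0, wg$estimate / wg$SE, NA_real_)
  wg$p.value <- ifelse(is.na(wg$t.ratio), NA_real_,
                       2 * stats::pt(-abs(wg$t.ratio), ns - 1))
  time_est <- mean(means)
  int_est <- if (length(means) == 2) diff(means) else NA_real_
  if (stats::sd(d) > 1e-12) {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    co <- summary(stats::lm(d ~ g))$coefficients
    tstat <- co[, "t value"]^2
    pv <- co[, "Pr(>|t|)"]
  } else {
    tstat <- c(NA_real_, if (abs(int_est) < 1e-12) 0 else Inf)
    pv <- c(NA_real_, NA_real_)
  }
  terms_df <- data.frame(
    term = c("time", "group:time"),
    statistic = unname(tstat[1:2]),
    df_num = 1, df_den = length(d) - length(means),
    p_value = unname(pv[1:2]))
  effect_report(terms_df,
                data.frame(term = c("time", "group:time"),
                           estimate = c(time_est, int_est),
                           se = NA_real_),
                wg, model = "mixed",
                note = "singular fit: paired fallback on subject differences")
}

#' Two-way ANCOVA with the number of analyzed slices as covariate
#'
#' Fits `value ~ group * time + covariate` with sum-to-zero contrasts and
#' reports type-III tests, the analysis used for depot masses where the
#' per-participant slice count co-determines the measured mass. A constant
#' covariate is dropped with a warning rather than failing.
#'
#' @inheritParams mixed_model_group_time
#' @param covariate column name of the covariate (default
#'   `"n_slices_analyzed"`).
#' @return an `effect_report` with `model = "ancova"`.
#' @export
ancova_group_time <- function(table, outcome, covariate = "n_slices_analyzed",
                              log_scale = FALSE) {
  dat <- prepare_cohort(table, outcome, log_scale)
  use_cov <- !is.null(covariate)
  if (use_cov && !covariate %in% names(dat))
    stop("covariate '", covariate, "' not present")
  if (use_cov && stats::sd(dat[[covariate]]) == 0) {
    warning("covariate '", covariate, "' is constant; dropped")
    use_cov <- FALSE
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  form <- if (use_cov)
    stats::as.formula(paste("value ~ group * time +", covariate))
  else value ~ group * time
  fit <- stats::lm(form, data = dat)
  rows_wanted <- c("group", "time", "group:time", if (use_cov) covariate)
  if (suppressWarnings(summary(fit)$sigma^2) > 1e-12 * stats::var(dat$value)) {
    an <- car::Anova(fit, type = 3)
    rows <- intersect(rows_wanted, rownames(an))
    terms_df <- data.frame(
      term = rows,
      statistic = an[rows, "F value"],
      df_num = an[rows, "Df"],
      df_den = stats::df.residual(fit),
      p_value = an[rows, "Pr(>F)"],
      row.names = NULL)
  } else {
    # perfectly fitted model (e.g. outcome proportional to the covariate):
    # F ratios are 0/0 for null terms; report SS-based verdicts instead
    terms_df <- do.call(rbind, lapply(rows_wanted, function(tm) {
      drop_fit <- stats::lm(stats::update(stats::formula(fit),
                                          stats::as.formula(paste("~ . -", tm))),
                            data = dat)
      ss <- sum(stats::residuals(drop_fit)^2) - sum(stats::residuals(fit)^2)
      null_term <- ss <= 1e-10 * stats::var(dat$value) * nrow(dat)
      data.frame(term = tm, statistic = if (null_term) 0 else Inf,
                 df_num = 1, df_den = stats::df.residual(fit),
                 p_value = if (null_term) 1 else 0)
    }))
  }
  est <- data.frame(term = names(stats::coef(fit)),
                    estimate = unname(stats::coef(fit)),
                    se = suppressWarnings(unname(sqrt(diag(stats::vcov(fit))))))
  wg <- tryCatch({
    emm <- emmeans::emmeans(fit, ~ time | group, data = dat)
    as.data.frame(emmeans::contrast(emm, method = "revpairwise",
                                    adjust = "none"))
  }, error = function(e) data.frame(), warning = function(w) data.frame())
  effect_report(terms_df, est, wg, model = "ancova",
                note = if (use_cov) paste("covariate:", covariate)
                       else "covariate dropped (constant)")
}

effect_report <- function(terms, estimates, within_group, model, note = "") {
  if (nrow(terms) && (any(terms$p_value < 0, na.rm = TRUE) ||
                      any(terms$p_value > 1, na.rm = TRUE)))
    stop("invalid p-values")
  structure(list(terms = terms, estimates = estimates,
                 within_group = within_group, model = model, note = note),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("<effect_report> %s model (%s)\n", x$model, x$note))
  print(x$terms, row.names = FALSE, digits = 4)
  if (nrow(x$within_group)) {
    cat("within-group ls-means contrasts:\n")
    print(x$within_group, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Extract one term's p-value from an effect report
#' @param report an `effect_report`.
#' @param term `"group"`, `"time"` or `"group:time"`.
#' @export
term_p_value <- function(report, term) {
  i <- match(term, report$terms$term)
  if (is.na(i)) return(NA_real_)
  report$terms$p_value[i]
}

#' Descriptive mean with 95 percent confidence interval
#'
#' t-based interval `mean +/- t(0.975, n-1) * sd / sqrt(n)`, the format used
#' for all descriptive cohort tables.
#'
#' @param values numeric vector, n >= 2.
#' @return named numeric: `mean`, `lower95`, `upper95`.
#' @export
descriptive_mean_ci <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, lower95 = m - half, upper95 = m + half)
}
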