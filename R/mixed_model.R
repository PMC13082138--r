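#' Mixed-effects analysis of classification scores
#'
#' Fits a linear mixed model to the long-format score table produced by
#' [sensitivity_grid()]:
#' `score ~ C(window, ref = 12 s) + C(rate, ref = 50 Hz) +
#' C(metric, ref = f1) + (1 | subject)`,
#' estimated by REML, with Wald z statistics and 95% confidence
#' intervals (`beta +/- 1.96 SE`). Scores are modeled in percent, so
#' coefficients read as percentage-point contrasts against the reference
#' levels. The subject random-intercept variance quantifies
#' inter-individual variability. All four metrics are stacked into one
#' response with a metric fixed effect; the induced correlation between
#' metrics of the same cell is a property of this design.
#'
#' @param metric_table Data frame with columns `subject_id`, `window_s`,
#'   `rate_hz`, `metric`, `score` (percent), e.g. from
#'   [sensitivity_grid()].
#' @param ref_window,ref_rate,ref_metric Reference levels for the three
#'   contrasts.
#' @return An object of class `metric_mixed_model` with a coefficient
#'   table (`term`, `beta`, `se`, `z`, `p`, `ci_lo`, `ci_hi`), the
#'   subject-intercept variance `group_var`, residual variance, a
#'   `singular` flag, and the underlying `lme4` fit.
#' @export
mixed_effects <- function(metric_table, ref_window = NULL, ref_rate = NULL,
                          ref_metric = "f1") {
  need <- c("subject_id", "window_s", "rate_hz", "metric", "score")
  missing_cols <- setdiff(need, names(metric_table))
  if (length(missing_cols))
    stop("metric_table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(metric_table)
  if (length(unique(df$subject_id)) < 3L)
    stop("mixed model needs at least 3 subjects")
  ref_window <- ref_window %||% max(df$window_s)
  ref_rate <- ref_rate %||% max(df$rate_hz)
  wl <- sort(unique(df$window_s)); rl <- sort(unique(df$rate_hz))
  df$window_f <- stats::relevel(factor(df$window_s, levels = wl),
                                ref = as.character(ref_window))
  df$rate_f <- stats::relevel(factor(df$rate_hz, levels = rl),
                              ref = as.character(ref_rate))
  df$metric_f <- stats::relevel(factor(df$metric), ref = ref_metric)
  terms <- c()
  if (nlevels(df$window_f) > 1L) terms <- c(terms, "window_f")
  if (nlevels(df$rate_f) > 1L) terms <- c(terms, "rate_f")
  if (nlevels(df$metric_f) > 1L) terms <- c(terms, "metric_f")
  if (!length(terms)) stop("no varying fixed effects in metric_table")
  form <- stats::as.formula(paste("score ~", paste(terms, collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular mixed-model fit (random-intercept variance ~ 0)")
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cf / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- data.frame(
    term = pretty_terms(names(cf), ref_window, ref_rate, ref_metric),
    beta = as.numeric(cf), se = as.numeric(se), z = as.numeric(z),
    p = 2 * stats::pnorm(-abs(as.numeric(z))),
    ci_lo = as.numeric(cf - 1.96 * se), ci_hi = as.numeric(cf + 1.96 * se),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 group_var = vc$vcov[vc$grp == "subject_id"],
                 residual_var = vc$vcov[vc$grp == "Residual"],
                 singular = singular, fit = fit),
            class = "metric_mixed_model")
}

pretty_terms <- function(nm, ref_window, ref_rate, ref_metric) {
  out <- nm
  out[nm == "(Intercept)"] <- "(Intercept)"
  i <- grepl("^window_f", nm)
  out[i] <- sprintf("window %s s vs. %s s", sub("^window_f", "", nm[i]),
                    ref_window)
  i <- grepl("^rate_f", nm)
  out[i] <- sprintf("rate %s Hz vs. %s Hz", sub("^rate_f", "", nm[i]),
                    ref_rate)
  i <- grepl("^metric_f", nm)
  out[i] <- sprintf("%s vs. %s", sub("^metric_f", "", nm[i]), ref_metric)
  out
}

#' @export
print.metric_mixed_model <- function(x, ...) {
  cat("Linear mixed model of classification scores (REML, Wald z)\n")
  df <- x$coefficients
  df$beta <- round(df$beta, 3); df$se <- round(df$se, 3)
  df$z <- round(df$z, 3)
  df$p <- signif(df$p, 3)
  df$ci <- sprintf("[%.3f, %.3f]", x$coefficients$ci_lo,
                   x$coefficients$ci_hi)
  print(df[, c("term", "beta", "se", "z", "p", "ci")], row.names = FALSE)
  cat(sprintf("subject random-intercept variance: %.3f (residual %.3f)%s\n",
              x$group_var, x$residual_var,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Simulate a score table with known fixed effects
#'
#' Generates a long-format metric table from a known linear model:
#' `score = baseline + window effect + rate effect + metric effect +
#' subject intercept + residual`. Used for parameter-recovery checks of
#' [mixed_effects()] (are the injected effects inside the fitted 95%
#' confidence intervals?).
#'
#' @param n_subjects Number of subjects.
#' @param window_effects Named numeric vector of percentage-point effects
#'   per window size (reference level should be 0).
#' @param rate_effects Named numeric vector per sampling rate.
#' @param metric_effects Named numeric vector per metric name.
#' @param baseline Grand mean score in percent.
#' @param subject_sd SD of the subject random intercept.
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @return A `metric_table` data frame.
#' @export
simulate_metric_table <- function(n_subjects = 10,
                                  window_effects = c("1" = -12, "2" = -7,
                                                     "4" = -3.5, "5" = -3,
                                                     "8" = -1.7, "12" = 0),
                                  rate_effects = c("5" = -8.8, "10" = -3.4,
                                                   "25" = -0.8, "50" = 0),
                                  metric_effects = c(accuracy = -3.3,
                                                     precision = 8.3,
                                                     recall = -3.3, f1 = 0),
                                  baseline = 80, subject_sd = 8,
                                  resid_sd = 5, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  subjects <- sprintf("sim%02d", seq_len(n_subjects))
  intercepts <- stats::rnorm(n_subjects, 0, subject_sd)
  grid <- expand.grid(subject_id = subjects,
                      window_s = as.numeric(names(window_effects)),
                      rate_hz = as.numeric(names(rate_effects)),
                      metric = names(metric_effects),
                      stringsAsFactors = FALSE)
  grid$score <- baseline +
    window_effects[as.character(grid$window_s)] +
    rate_effects[as.character(grid$rate_hz)] +
    metric_effects[grid$metric] +
    intercepts[match(grid$subject_id, subjects)] +
    stats::rnorm(nrow(grid), 0, resid_sd)
  class(grid) <- c("metric_table", class(grid))
  grid
}
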