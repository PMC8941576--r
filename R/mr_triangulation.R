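#' @title One-sample Mendelian randomization triangulation
#' @description
#' Composes the expected genetic effect on NAFLD as the product of the
#' gene-exposure effect (mg/dl SUA per allele) and the log of the
#' exposure-outcome odds ratio (per mg/dl), estimates the observed
#' per-allele effect by logistic regression, and compares the two with the
#' Altman-Bland interaction test. Includes a normal-approximation power
#' calculation for per-allele effects.
#' @name mr_triangulation
NULL

#' Log-odds standard error from a printed odds-ratio CI
#'
#' SE = (ln upper - ln lower) / (2 z), with z the two-sided normal
#' critical value for the interval's level (1.959964 at 95% by default;
#' pass `z = 1.96` to reproduce hand calculations done at two decimals).
#'
#' @param ci_low,ci_high positive odds-ratio bounds, `ci_low <= ci_high`.
#' @param level confidence level of the interval.
#' @param z optional explicit critical value overriding `level`.
#' @return standard error on the log-odds scale.
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95, z = NULL) {
  if (any(ci_low <= 0) || any(ci_high <= 0) || any(ci_low > ci_high))
    stopf("CI bounds must be positive with ci_low <= ci_high",
          class = "suamr_invalid_parameter")
  z <- z %||% z_crit(level)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

#' Odds-ratio CI from a log-odds standard error
#'
#' Inverse of [se_from_ci()] around a point odds ratio.
#'
#' @param or point odds ratio (> 0).
#' @param se log-odds standard error (>= 0).
#' @inheritParams se_from_ci
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
ci_from_se <- function(or, se, level = 0.95, z = NULL) {
  if (or <= 0 || se < 0)
    stopf("`or` must be positive and `se` nonnegative",
          class = "suamr_invalid_parameter")
  z <- z %||% z_crit(level)
  c(or * exp(-z * se), or * exp(z * se))
}

#' Expected genetic effect on the outcome
#'
#' The per-allele log-odds expected under a causal exposure effect:
#' beta_E = beta_GB x ln(OR_BD), where beta_GB is the per-allele exposure
#' effect (mg/dl) and OR_BD the exposure-outcome odds ratio per mg/dl.
#'
#' @param beta_gb per-allele effect on SUA, mg/dl.
#' @param or_bd odds ratio per mg/dl SUA (> 0).
#' @return list with `log_odds` and `or`.
#' @examples
#' expected_effect(0.22, 1.18)$or  # ~1.037
#' @export
expected_effect <- function(beta_gb, or_bd) {
  assert_number(beta_gb, "beta_gb")
  assert_number(or_bd, "or_bd", lower = 0, strict_lower = TRUE)
  log_odds <- beta_gb * log(or_bd)
  list(log_odds = log_odds, or = exp(log_odds))
}

#' Observed per-allele (or per-score-unit) effect on NAFLD
#'
#' Logistic regression of the outcome on the instrument column plus the
#' adjustment covariates.
#'
#' @param cohort participant table with the instrument merged in.
#' @param instrument column name of the additive allele count or genetic
#'   score.
#' @param adjustment covariate names.
#' @param outcome binary outcome column.
#' @return an [effect_estimate()] on the per-allele scale.
#' @export
observed_effect <- function(cohort, instrument, adjustment = character(0),
                            outcome = "nafld_followup") {
  if (length(unique(stats::na.omit(cohort[[instrument]]))) < 2)
    stopf("instrument `%s` is degenerate", instrument,
          class = "suamr_degenerate_instrument")
  keep <- stats::complete.cases(cohort[, c(outcome, instrument, adjustment),
                                       drop = FALSE])
  data <- cohort[keep, , drop = FALSE]
  fit <- fit_logistic(data, outcome, c(instrument, adjustment))
  effect_from_fit(fit, instrument, scale = "per allele")
}

#' Altman-Bland interaction test
#'
#' z = (b1 - b2) / sqrt(se1^2 + se2^2), with a two-sided normal P value.
#'
#' @param b1,b2 the two estimates on a common (log-odds) scale.
#' @param se1,se2 their standard errors; not both zero.
#' @return list with `z` and `p`.
#' @export
altman_bland_test <- function(b1, se1, b2, se2) {
  assert_number(b1, "b1"); assert_number(b2, "b2")
  assert_number(se1, "se1", lower = 0); assert_number(se2, "se2", lower = 0)
  if (se1^2 + se2^2 <= 0)
    stopf("both standard errors are zero", class = "suamr_invalid_parameter")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare observed and expected genetic effects
#'
#' Assembles the expected effect from the instrument's exposure effect and
#' the exposure-outcome odds ratio, then tests the observed estimate
#' against it. Under `fixed_expected` (default) the expected effect is
#' treated as a known constant with zero standard error, reproducing the
#' degenerate expected interval of the source analysis; under
#' `delta_method` its SE is propagated as |ln(OR_BD)| x SE(beta_GB), the
#' exposure-outcome estimate treated as fixed.
#'
#' @param instrument an `instrument_summary` (see [fit_instrument()]), or
#'   a list with at least `snp`, `beta` and `se` for a score instrument.
#' @param exposure_outcome an [effect_estimate()] of the per-mg/dl odds
#'   ratio of NAFLD (scale must mention mg/dl).
#' @param observed an [effect_estimate()] of the per-allele effect.
#' @param mode `"fixed_expected"` or `"delta_method"`.
#' @return object of class `mr_comparison`.
#' @export
mr_compare <- function(instrument, exposure_outcome, observed,
                       mode = c("fixed_expected", "delta_method")) {
  mode <- match.arg(mode)
  if (!grepl("mg", exposure_outcome$scale, fixed = TRUE))
    stopf("exposure-outcome effect must be on the per-mg/dl scale (got `%s`)",
          exposure_outcome$scale, class = "suamr_invalid_combination")
  if (!grepl("allele", observed$scale, fixed = TRUE))
    stopf("observed effect must be per allele (got `%s`)", observed$scale,
          class = "suamr_invalid_combination")
  or_bd <- exposure_outcome$estimate
  exp_eff <- expected_effect(instrument$beta, or_bd)
  expected_se <- switch(mode,
    fixed_expected = 0,
    delta_method = abs(log(or_bd)) * instrument$se)
  ab <- altman_bland_test(observed$beta, observed$se,
                          exp_eff$log_odds, expected_se)
  structure(
    list(instrument = instrument$snp, observed = observed,
         expected_beta = exp_eff$log_odds, expected_or = exp_eff$or,
         expected_se = expected_se,
         expected_ci = ci_from_se(exp_eff$or, expected_se),
         z = ab$z, p = ab$p, propagation_mode = mode),
    class = "mr_comparison")
}

#' @export
print.mr_comparison <- function(x, ...) {
  cat(sprintf("MR comparison for %s (%s)\n", x$instrument, x$propagation_mode))
  cat(sprintf("  observed OR %.3f (%.3f, %.3f)\n",
              x$observed$estimate, x$observed$ci_low, x$observed$ci_high))
  cat(sprintf("  expected OR %.3f (%.3f, %.3f)\n",
              x$expected_or, x$expected_ci[1], x$expected_ci[2]))
  cat(sprintf("  difference: z = %.3f, P = %.3g\n", x$z, x$p))
  invisible(x)
}

#' Approximate power for a per-allele association test
#'
#' Normal-approximation power under an additive model: the log-odds SE is
#' approximated by 1 / sqrt(N v phi (1 - phi)) with v = 2 q (1 - q) the
#' additive genotype variance and phi the case fraction. Documented as
#' approximate; the method of the source analysis is unstated.
#'
#' @param n_cases,n_controls counts.
#' @param maf risk-allele frequency in (0, 1).
#' @param or target odds ratio per allele (> 0).
#' @param alpha two-sided significance level.
#' @return power, a fraction in (0, 1); equals `alpha` when `or = 1`.
#' @export
power_genetic <- function(n_cases, n_controls, maf, or, alpha = 0.05) {
  assert_number(n_cases, "n_cases", lower = 1)
  assert_number(n_controls, "n_controls", lower = 1)
  assert_number(maf, "maf", 0, 1, TRUE, TRUE)
  assert_number(or, "or", lower = 0, strict_lower = TRUE)
  assert_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  n <- n_cases + n_controls
  phi <- n_cases / n
  v <- 2 * maf * (1 - maf)
  se <- 1 / sqrt(n * v * phi * (1 - phi))
  za <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(or)) / se
  stats::pnorm(ncp - za) + stats::pnorm(-ncp - za)
}
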