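#' @title Hepatic necroinflammation and fibrosis progression markers
#' @description
#' Among incident-NAFLD participants, relates SUA quartiles to hepatic
#' necroinflammation (ALT, GGT) and estimated fibrosis (APRI, FIB-4):
#' covariance-adjusted mean differences versus the lowest quartile, and
#' odds ratios of elevated markers with quartile, per-mg/dl and subgroup
#' effects. The quartile scheme is recomputed within the NAFLD subgroup.
#' @name progression_markers
NULL

# Adjustment sets for the marker models. The covariance (mean-difference)
# models omit age for every marker; the elevated-marker OR models include
# age except for FIB-4, whose formula already contains age.
progression_adjustment <- function(marker, model = c("mean_difference", "odds")) {
  model <- match.arg(model)
  base <- c("sex", "bmi", "smoking", "drinking", "physical_activity",
            "cre", "fpg", "history_hypertension", "history_chd",
            "history_diabetes")
  if (model == "odds" && marker != "FIB4") c("age", base) else base
}

# Pull the marker column, computing APRI/FIB-4 from the labs when needed.
marker_values <- function(cohort, marker, ast_uln = 40) {
  switch(marker,
    ALT = cohort$alt,
    GGT = cohort$ggt,
    APRI = compute_apri(cohort$ast, cohort$plt, ast_uln = ast_uln),
    FIB4 = compute_fib4(cohort$age, cohort$ast, cohort$alt, cohort$plt),
    stopf("unknown marker `%s`", marker, class = "suamr_invalid_parameter"))
}

#' Covariance-adjusted mean marker differences by SUA quartile
#'
#' Linear model of the marker on quartile indicators (Q1 reference) plus
#' covariates; returns the Q2-Q4 coefficients as adjusted mean differences
#' with Wald confidence intervals, and the Q1 row fixed at zero with a
#' degenerate interval.
#'
#' @param nafld_cohort participant table restricted to incident-NAFLD
#'   participants.
#' @param marker `"ALT"`, `"GGT"`, `"APRI"` or `"FIB4"`.
#' @param scheme quartile scheme computed within this subgroup (see
#'   [compute_quartile_scheme()]); computed on the fly when NULL.
#' @param adjustment covariate names; defaults to the marker's standard
#'   covariance-model set (no age).
#' @param ast_uln AST upper limit of normal for APRI.
#' @return data frame with one row per quartile: `quartile`, `difference`,
#'   `ci_low`, `ci_high`, `n`; covariates recorded in the
#'   `"covariates"` attribute.
#' @export
adjusted_mean_differences <- function(nafld_cohort, marker, scheme = NULL,
                                      adjustment = NULL, ast_uln = 40) {
  if (is.null(scheme)) scheme <- compute_quartile_scheme(nafld_cohort)
  if (is.null(adjustment))
    adjustment <- progression_adjustment(marker, "mean_difference")
  data <- nafld_cohort
  data$.marker <- marker_values(data, marker, ast_uln)
  if (stats::var(data$.marker, na.rm = TRUE) == 0)
    stopf("marker `%s` has zero variance", marker, class = "suamr_fitting_error")
  data$.quartile <- factor(
    assign_quartiles(data[[scheme$variable]], data$sex, scheme), levels = 1:4)
  keep <- stats::complete.cases(data[, c(".marker", ".quartile", adjustment),
                                     drop = FALSE])
  data <- prepare_model_frame(data[keep, , drop = FALSE])
  fm <- stats::reformulate(c(".quartile", adjustment), response = ".marker")
  fit <- stats::lm(fm, data = data)
  ct <- stats::coef(summary(fit))
  z <- z_crit()
  rows <- lapply(2:4, function(k) {
    term <- sprintf(".quartile%d", k)
    b <- ct[term, 1]; se <- ct[term, 2]
    data.frame(quartile = k, difference = b,
               ci_low = b - z * se, ci_high = b + z * se,
               n = sum(data$.quartile == k))
  })
  out <- rbind(
    data.frame(quartile = 1L, difference = 0, ci_low = 0, ci_high = 0,
               n = sum(data$.quartile == 1)),
    do.call(rbind, rows))
  attr(out, "covariates") <- adjustment
  attr(out, "marker") <- marker
  out
}

#' Odds ratios of elevated markers by SUA quartile and per mg/dl
#'
#' Flags elevation via [classify_elevated()], then fits (i) the quartile
#' logistic model, (ii) a per-mg/dl model, and (iii) per-mg/dl models in
#' sex and BMI-category subgroups. For FIB-4 the adjustment set excludes
#' age (age already enters the score's formula); this is recorded in the
#' result's `covariates` field.
#'
#' @inheritParams adjusted_mean_differences
#' @param bmi_cutoff overweight threshold for the BMI subgroups.
#' @return list with `percent_elevated` (per-quartile percentages),
#'   `quartile_fit` (a [fit_quartile_or()] result), `per_mgdl` (an
#'   [effect_estimate()]), `subgroups` (named list of per-mg/dl
#'   estimates), `covariates`, and `marker`.
#' @export
elevated_marker_or <- function(nafld_cohort, marker, scheme = NULL,
                               adjustment = NULL, ast_uln = 40,
                               bmi_cutoff = 24) {
  if (is.null(scheme)) scheme <- compute_quartile_scheme(nafld_cohort)
  if (is.null(adjustment))
    adjustment <- progression_adjustment(marker, "odds")
  data <- nafld_cohort
  vals <- marker_values(data, marker, ast_uln)
  data$.elevated <- classify_elevated(marker, vals, data$sex)
  q <- assign_quartiles(data[[scheme$variable]], data$sex, scheme)
  pct <- vapply(1:4, function(k)
    100 * mean(data$.elevated[q == k], na.rm = TRUE), numeric(1))
  qfit <- fit_quartile_or(data, outcome = ".elevated", scheme = scheme,
                          adjustment = adjustment)
  per_mgdl <- fit_per_unit_or(data, outcome = ".elevated",
                              adjustment = adjustment)
  data$bmi_category <- bmi_category(data$bmi, cutoff = bmi_cutoff)
  sub_sex <- stratified_analysis(data, "sex", fit_per_unit_or,
                                 adjustment = adjustment,
                                 outcome = ".elevated")
  sub_bmi <- stratified_analysis(data, "bmi_category", fit_per_unit_or,
                                 adjustment = adjustment,
                                 outcome = ".elevated")
  list(percent_elevated = stats::setNames(pct, paste0("Q", 1:4)),
       quartile_fit = qfit, per_mgdl = per_mgdl,
       subgroups = c(sub_sex, sub_bmi),
       covariates = adjustment, marker = marker)
}
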