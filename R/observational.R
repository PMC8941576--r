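#' @title Observational SUA-NAFLD association models
#' @description
#' Sex-specific exposure quartile construction and the logistic models of
#' the main association analysis: quartile odds ratios under nested
#' adjustment sets, trend tests, per-unit odds ratios on the mg/dl and
#' umol/l scales, and stratified analyses by sex or BMI category.
#' @name observational_association
NULL

#' Named adjustment sets
#'
#' The nested covariate sets of the main analysis. `univariate` has no
#' covariates; `age_sex` adjusts for age and sex; `model1` adds BMI,
#' smoking, drinking and physical activity; `model2` further adds history
#' of CHD, hypertension and diabetes and the ALT, creatinine and fasting
#' glucose concentrations.
#'
#' @param name one of `"univariate"`, `"age_sex"`, `"model1"`, `"model2"`,
#'   or a character vector of covariate names for a custom set.
#' @return character vector of covariate names (possibly empty).
#' @export
adjustment_set <- function(name = c("univariate", "age_sex", "model1", "model2")) {
  if (length(name) > 1 && !all(name %in% c("univariate", "age_sex",
                                           "model1", "model2")))
    return(name)  # custom covariate vector
  name <- match.arg(name)
  switch(name,
    univariate = character(0),
    age_sex = c("age", "sex"),
    model1 = c("age", "sex", "bmi", "smoking", "drinking",
               "physical_activity"),
    model2 = c("age", "sex", "bmi", "smoking", "drinking",
               "physical_activity", "history_chd", "history_hypertension",
               "history_diabetes", "alt", "cre", "fpg")
  )
}

#' Compute a sex-specific quartile scheme
#'
#' Cutoffs are the within-sex 25th/50th/75th percentiles (linear
#' interpolation between order statistics, R's default quantile type 7).
#' Assignment is left-closed: Q1 is value < c1; Qk is c(k-1) <= value < ck;
#' Q4 is value >= c3.
#'
#' @param cohort participant table.
#' @param variable column to quartile (default `"sua"`).
#' @return object of class `quartile_scheme` with per-sex cutoffs.
#' @export
compute_quartile_scheme <- function(cohort, variable = "sua") {
  cutoffs <- lapply(c(male = "male", female = "female"), function(s) {
    v <- cohort[[variable]][cohort$sex == s]
    v <- v[!is.na(v)]
    if (length(v) < 4)
      stopf("fewer than 4 non-missing `%s` values for sex `%s`",
            variable, s, class = "suamr_insufficient_data")
    cs <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    if (any(diff(cs) <= 0))
      stopf("quartile cutoffs for sex `%s` are not strictly increasing", s,
            class = "suamr_insufficient_data")
    cs
  })
  structure(list(variable = variable, cutoffs = cutoffs),
            class = "quartile_scheme")
}

#' Manually specify a quartile scheme
#'
#' @param male,female strictly increasing cutoff triples (mg/dl).
#' @param variable variable name the scheme applies to.
#' @return object of class `quartile_scheme`.
#' @export
quartile_scheme <- function(male, female, variable = "sua") {
  for (cs in list(male, female)) {
    if (length(cs) != 3 || any(diff(cs) <= 0))
      stopf("cutoffs must be strictly increasing triples",
            class = "suamr_invalid_parameter")
  }
  structure(list(variable = variable,
                 cutoffs = list(male = male, female = female)),
            class = "quartile_scheme")
}

#' @export
print.quartile_scheme <- function(x, ...) {
  cat(sprintf("Quartile scheme for `%s` (left-closed at cutoffs)\n", x$variable))
  for (s in names(x$cutoffs))
    cat(sprintf("  %s: %s\n", s, paste(format(x$cutoffs[[s]]), collapse = ", ")))
  invisible(x)
}

#' Assign quartiles under a scheme
#'
#' @param values numeric values of the scheme's variable.
#' @param sex `"male"`/`"female"`, recycled against `values`.
#' @param scheme a `quartile_scheme`.
#' @return integer quartile 1..4 (NA where value missing).
#' @export
assign_quartiles <- function(values, sex, scheme) {
  if (length(sex) == 1L) sex <- rep(sex, length(values))
  q <- rep(NA_integer_, length(values))
  for (s in names(scheme$cutoffs)) {
    i <- which(sex == s & !is.na(values))
    # findInterval counts cutoffs <= value, giving the left-closed rule
    q[i] <- 1L + findInterval(values[i], scheme$cutoffs[[s]])
  }
  q
}

# Shared logistic fitting with explicit degenerate-outcome and separation
# handling. Returns the glm fit.
fit_logistic <- function(data, outcome, terms) {
  y <- data[[outcome]]
  if (length(unique(stats::na.omit(as.numeric(y)))) < 2)
    stopf("outcome `%s` is degenerate (all one level); logistic fit would separate",
          outcome, class = "suamr_separation_error")
  fm <- stats::reformulate(terms, response = outcome)
  data <- prepare_model_frame(data)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fm, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged)
    stopf("logistic model `%s` did not converge", deparse(fm),
          class = "suamr_fitting_error")
  coefs <- stats::coef(fit)
  if (sep && any(abs(coefs[-1]) > 10, na.rm = TRUE))
    stopf("complete or quasi-complete separation in model `%s`", deparse(fm),
          class = "suamr_separation_error")
  fit
}

#' Quartile odds ratios for a binary outcome
#'
#' Fits a maximum-likelihood logistic regression of the outcome on quartile
#' indicator variables (Q1 reference) plus the adjustment covariates, with
#' Wald confidence intervals. The trend P value comes from a separate fit
#' replacing the indicators with the ordinal quartile index (1-4, or the
#' within-quartile exposure medians when `trend = "median"`) entered as a
#' continuous covariate.
#'
#' @param cohort participant table.
#' @param outcome binary outcome column (default `"nafld_followup"`).
#' @param scheme a `quartile_scheme` for the exposure.
#' @param adjustment covariate names (see [adjustment_set()]).
#' @param trend `"index"` (default) or `"median"`.
#' @return object of class `quartile_fit`: a list with `estimates` (a data
#'   frame of Q2-Q4 odds ratios with CI and P), `trend_p`, `covariates`,
#'   and `n`.
#' @export
fit_quartile_or <- function(cohort, outcome = "nafld_followup", scheme,
                            adjustment = character(0),
                            trend = c("index", "median")) {
  trend <- match.arg(trend)
  q <- assign_quartiles(cohort[[scheme$variable]], cohort$sex, scheme)
  data <- cohort
  data$.quartile <- factor(q, levels = 1:4)
  keep <- stats::complete.cases(data[, c(outcome, ".quartile", adjustment),
                                     drop = FALSE])
  data <- data[keep, , drop = FALSE]
  fit <- fit_logistic(data, outcome, c(".quartile", adjustment))
  ests <- lapply(2:4, function(k)
    effect_from_fit(fit, sprintf(".quartile%d", k),
                    scale = sprintf("quartile-%d vs Q1", k)))
  est_df <- do.call(rbind, lapply(seq_along(ests), function(i) {
    d <- as.data.frame(ests[[i]]); d$quartile <- i + 1L; d
  }))
  data$.qtrend <- if (trend == "index") {
    as.numeric(as.character(data$.quartile))
  } else {
    med <- tapply(data[[scheme$variable]], data$.quartile, stats::median,
                  na.rm = TRUE)
    as.numeric(med[as.character(data$.quartile)])
  }
  tfit <- fit_logistic(data, outcome, c(".qtrend", adjustment))
  trend_p <- stats::coef(summary(tfit))[".qtrend", 4]
  structure(list(estimates = est_df, trend_p = trend_p,
                 covariates = adjustment, outcome = outcome,
                 n = nrow(data)),
            class = "quartile_fit")
}

#' @export
print.quartile_fit <- function(x, ...) {
  cat(sprintf("Quartile logistic fit of `%s` (n = %d)\n", x$outcome, x$n))
  cat(sprintf("  adjusted for: %s\n",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)"))
  df <- x$estimates
  for (i in seq_len(nrow(df)))
    cat(sprintf("  Q%d vs Q1: OR %.2f (%.2f, %.2f), P = %.3g\n",
                df$quartile[i], df$estimate[i], df$ci_low[i], df$ci_high[i],
                df$p[i]))
  cat(sprintf("  P for trend = %.3g\n", x$trend_p))
  invisible(x)
}

#' Per-unit odds ratio for a continuous exposure
#'
#' Logistic fit with the exposure continuous; the coefficient is reported
#' on the requested unit scale. For the same fit the two scales satisfy
#' OR(mg/dl) = OR(umol/l)^59.5 exactly.
#'
#' @param cohort participant table.
#' @param outcome binary outcome column.
#' @param adjustment covariate names.
#' @param unit `"mg_per_dl"` (default) or `"umol_per_l"`.
#' @param exposure exposure column, mg/dl (default `"sua"`).
#' @return an [effect_estimate()] on the requested scale.
#' @export
fit_per_unit_or <- function(cohort, outcome = "nafld_followup",
                            adjustment = character(0),
                            unit = c("mg_per_dl", "umol_per_l"),
                            exposure = "sua") {
  unit <- match.arg(unit)
  keep <- stats::complete.cases(cohort[, c(outcome, exposure, adjustment),
                                       drop = FALSE])
  data <- cohort[keep, , drop = FALSE]
  fit <- fit_logistic(data, outcome, c(exposure, adjustment))
  ct <- stats::coef(summary(fit))
  beta <- ct[exposure, 1]; se <- ct[exposure, 2]; p <- ct[exposure, 4]
  if (unit == "umol_per_l") { beta <- beta / 59.5; se <- se / 59.5 }
  z <- z_crit()
  effect_estimate(scale = sprintf("per %s", sub("_", " ", sub("_per_", "/", unit))),
                  beta = beta, se = se,
                  ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                  p = p, n = nrow(data))
}

#' Run an analysis within strata
#'
#' Splits the cohort by sex or BMI category and reruns the supplied
#' analysis per stratum, dropping the stratification variable (and, for
#' sex, the `sex` covariate) from the adjustment set. `bmi_category` is
#' derived from `bmi` when absent.
#'
#' @param cohort participant table.
#' @param strata `"sex"` or `"bmi_category"`.
#' @param fun analysis function taking `(cohort, ..., adjustment = )`.
#' @param adjustment covariate names before stratification adjustment.
#' @param ... passed through to `fun`.
#' @param bmi_cutoff overweight threshold used when deriving `bmi_category`.
#' @return named list of per-stratum results.
#' @export
stratified_analysis <- function(cohort, strata = c("sex", "bmi_category"),
                                fun, adjustment = character(0), ...,
                                bmi_cutoff = 24) {
  strata <- match.arg(strata)
  if (strata == "bmi_category" && !"bmi_category" %in% names(cohort))
    cohort$bmi_category <- bmi_category(cohort$bmi, cutoff = bmi_cutoff)
  adj <- setdiff(adjustment, strata)
  groups <- split(cohort, cohort[[strata]])
  if (any(vapply(groups, nrow, integer(1)) == 0))
    stopf("empty stratum in `%s`", strata, class = "suamr_insufficient_data")
  lapply(groups, function(g) fun(g, ..., adjustment = adj))
}
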