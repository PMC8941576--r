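#' Effect estimate on a stated scale
#'
#' Lightweight container for a single regression coefficient: a log-odds or
#' linear coefficient together with its standard error, Wald confidence
#' interval on the reported scale, two-sided P value and analyzed count.
#'
#' @param scale descriptor of the scale, e.g. `"per mg/dl"`, `"quartile-4 vs Q1"`,
#'   `"per allele"`.
#' @param beta coefficient (log-odds for logistic fits).
#' @param se standard error of `beta`; must be positive.
#' @param ci_low,ci_high confidence bounds on the reported scale (odds-ratio
#'   scale for logistic effects).
#' @param p two-sided P value.
#' @param n number of records used in the fit.
#' @param estimate point estimate on the reported scale (`exp(beta)` for
#'   odds ratios; `beta` itself for linear effects).
#' @return an object of class `effect_estimate`.
#' @export
effect_estimate <- function(scale, beta, se, ci_low, ci_high, p, n,
                            estimate = exp(beta)) {
  assert_number(beta, "beta")
  assert_number(se, "se", lower = 0)
  assert_number(p, "p", lower = 0, upper = 1)
  if (!(ci_low <= estimate && estimate <= ci_high))
    stopf("confidence bounds must bracket the point estimate",
          class = "suamr_invalid_parameter")
  structure(
    list(scale = scale, beta = beta, se = se, estimate = estimate,
         ci_low = ci_low, ci_high = ci_high, p = p, n = n),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Effect (%s): %.3f (95%% CI %.3f, %.3f), P = %.3g, n = %d\n",
              x$scale, x$estimate, x$ci_low, x$ci_high, x$p, as.integer(x$n)))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(scale = x$scale, estimate = x$estimate, beta = x$beta,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             p = x$p, n = x$n, stringsAsFactors = FALSE)
}

# Build an effect_estimate from one row of a glm/lm coefficient table.
effect_from_fit <- function(fit, term, scale, exponentiate = TRUE,
                            level = 0.95) {
  ct <- stats::coef(summary(fit))
  if (!term %in% rownames(ct))
    stopf("term `%s` absent from fitted model (aliased or dropped)", term,
          class = "suamr_fitting_error")
  beta <- ct[term, 1]; se <- ct[term, 2]; p <- ct[term, 4]
  z <- z_crit(level)
  lo <- beta - z * se; hi <- beta + z * se
  n <- length(stats::fitted(fit))
  if (exponentiate) {
    effect_estimate(scale, beta, se, exp(lo), exp(hi), p, n)
  } else {
    effect_estimate(scale, beta, se, lo, hi, p, n, estimate = beta)
  }
}
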