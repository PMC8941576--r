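`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = "suamr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "suamr_error")))
}

#' Two-sided normal critical value
#'
#' @param level confidence level, e.g. 0.95.
#' @return the z such that `level` of the normal mass lies within +/- z.
#' @keywords internal
z_crit <- function(level = 0.95) {
  stats::qnorm(1 - (1 - level) / 2)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    stopf("`%s` must be a finite number in %s%s, %s%s (got %s)",
          name, if (strict_lower) "(" else "[", format(lower),
          format(upper), if (strict_upper) ")" else "]",
          paste(format(x), collapse = ","),
          class = "suamr_invalid_parameter")
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x)))
    stopf("`%s` must be TRUE or FALSE", name, class = "suamr_invalid_parameter")
  invisible(x)
}

# Coerce the categorical covariates used across all models to factors with
# fixed reference levels (male, never) so coefficients are comparable.
prepare_model_frame <- function(data) {
  if ("sex" %in% names(data))
    data$sex <- factor(data$sex, levels = c("male", "female"))
  for (v in c("smoking", "drinking")) {
    if (v %in% names(data))
      data[[v]] <- factor(data[[v]], levels = c("never", "quit", "current"))
  }
  data
}
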