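#' @title Genetic instrument validation
#' @description
#' Validates the two urate-transporter SNPs as instruments for SUA:
#' Hardy-Weinberg equilibrium testing, additive/dominant/codominant
#' genotype coding, adjusted per-allele linear regressions on SUA with
#' variance-explained diagnostics, the unweighted genetic score, and
#' confounder-balance checks.
#' @name genetic_instruments
NULL

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom Pearson test of observed genotype counts against
#' the HWE-expected counts implied by the sample allele frequency.
#'
#' @param counts integer vector `(n0, n1, n2)` of common-homozygote,
#'   heterozygote and rare-homozygote counts.
#' @return list with `chisq`, `p` and the estimated risk-allele frequency
#'   `q`.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: chisq 0, p 1
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0) || sum(counts) == 0)
    stopf("`counts` must be three nonnegative genotype counts with a positive total",
          class = "suamr_invalid_input")
  n <- sum(counts)
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (any(expected == 0)) {   # monomorphic sample: no departure measurable
    return(list(chisq = 0, p = 1, q = q))
  }
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       q = q)
}

#' Code genotypes under a genetic model
#'
#' @param counts allele counts in {0, 1, 2}; NA propagates.
#' @param model `"additive"` (0/1/2), `"dominant"` (carrier indicator) or
#'   `"codominant"` (two indicator columns, common-homozygote reference).
#' @return numeric vector, or a two-column matrix (`het`, `hom_rare`) for
#'   the codominant model.
#' @export
code_genotypes <- function(counts, model = c("additive", "dominant",
                                             "codominant")) {
  model <- match.arg(model)
  if (!all(counts %in% c(0, 1, 2) | is.na(counts)))
    stopf("allele counts must be 0, 1, 2 or NA", class = "suamr_invalid_input")
  switch(model,
    additive = as.numeric(counts),
    dominant = as.numeric(counts > 0),
    codominant = cbind(het = as.numeric(counts == 1),
                       hom_rare = as.numeric(counts == 2)))
}

#' Fit a single-SNP instrument on SUA
#'
#' Linear regression of SUA (mg/dl) on the additive allele count plus
#' covariates. Variance explained is the squared partial correlation of
#' the genotype term, t^2 / (t^2 + df), after covariate adjustment; with
#' `variance_explained = "unadjusted"` it is the R^2 of the
#' genotype-only regression. Hardy-Weinberg equilibrium is evaluated among
#' NAFLD-free participants by default.
#'
#' @param cohort participant table.
#' @param genotypes genotype table (`participant_id`, one column per SNP).
#' @param snp genotype column name, e.g. `"snp1"`.
#' @param adjustment covariate names.
#' @param variance_explained `"partial"` (default) or `"unadjusted"`.
#' @param hwe_subset `"nafld_free"` (default) or `"all"`.
#' @return object of class `instrument_summary`: snp id, per-allele `beta`
#'   (mg/dl), `se`, `p`, `variance_explained`, `hwe_p`, `call_rate`, `n`,
#'   and the covariates used.
#' @export
fit_instrument <- function(cohort, genotypes, snp,
                           adjustment = character(0),
                           variance_explained = c("partial", "unadjusted"),
                           hwe_subset = c("nafld_free", "all")) {
  variance_explained <- match.arg(variance_explained)
  hwe_subset <- match.arg(hwe_subset)
  data <- merge(cohort, genotypes, by.x = "id", by.y = "participant_id")
  g <- data[[snp]]
  call_rate <- mean(!is.na(g))
  if (length(unique(stats::na.omit(g))) < 2)
    stopf("SNP `%s` is monomorphic in this cohort", snp,
          class = "suamr_degenerate_instrument")
  data$.g <- code_genotypes(g, "additive")
  keep <- stats::complete.cases(data[, c("sua", ".g", adjustment),
                                     drop = FALSE])
  data <- prepare_model_frame(data[keep, , drop = FALSE])
  fm <- stats::reformulate(c(".g", adjustment), response = "sua")
  fit <- stats::lm(fm, data = data)
  ct <- stats::coef(summary(fit))
  beta <- ct[".g", 1]; se <- ct[".g", 2]; p <- ct[".g", 4]
  ve <- if (variance_explained == "partial") {
    tval <- ct[".g", 3]
    tval^2 / (tval^2 + fit$df.residual)
  } else {
    summary(stats::lm(sua ~ .g, data = data))$r.squared
  }
  hwe_rows <- if (hwe_subset == "nafld_free" && "nafld_followup" %in% names(data))
    data$.g[!data$nafld_followup %in% TRUE] else data$.g
  hwe <- hwe_test(tabulate(factor(hwe_rows, levels = 0:2), nbins = 3))
  structure(
    list(snp = snp, beta = beta, se = se, p = p,
         variance_explained = ve, hwe_p = hwe$p, call_rate = call_rate,
         n = nrow(data), covariates = adjustment),
    class = "instrument_summary")
}

#' @export
print.instrument_summary <- function(x, ...) {
  cat(sprintf(
    "Instrument %s: beta %.3f mg/dl per allele (SE %.3f, P = %.3g)\n",
    x$snp, x$beta, x$se, x$p))
  cat(sprintf("  variance explained %.2f%%, HWE P = %.3g, call rate %.3f, n = %d\n",
              100 * x$variance_explained, x$hwe_p, x$call_rate, x$n))
  invisible(x)
}

#' Unweighted genetic score
#'
#' Count of SUA-increasing alleles across the two SNPs (0-4). Missing
#' either SNP gives a missing score.
#'
#' @param genotypes genotype table with `snp1` and `snp2` allele counts.
#' @return integer vector of scores.
#' @export
build_genetic_score <- function(genotypes) {
  s <- genotypes$snp1 + genotypes$snp2
  as.integer(s)
}

#' Confounder balance across genotype
#'
#' Tests each covariate for association with the additive allele count:
#' linear regression for continuous covariates, Pearson chi-square of the
#' covariate-by-genotype contingency table for categorical ones. A
#' constant covariate is skipped with a note.
#'
#' @param cohort participant table.
#' @param genotypes genotype table.
#' @param snp genotype column.
#' @param covariates named character vector: names are covariate columns,
#'   values `"continuous"` or `"categorical"`.
#' @return data frame with `covariate`, `type`, `statistic`, `p`, `note`.
#' @export
confounder_balance <- function(cohort, genotypes, snp, covariates) {
  data <- merge(cohort, genotypes, by.x = "id", by.y = "participant_id")
  g <- code_genotypes(data[[snp]], "additive")
  rows <- lapply(names(covariates), function(v) {
    x <- data[[v]]
    type <- covariates[[v]]
    if (length(unique(stats::na.omit(x))) < 2) {
      warning(sprintf("covariate `%s` is constant; skipped", v), call. = FALSE)
      return(data.frame(covariate = v, type = type, statistic = NA_real_,
                        p = NA_real_, note = "constant; skipped"))
    }
    if (type == "continuous") {
      ct <- stats::coef(summary(stats::lm(x ~ g)))
      data.frame(covariate = v, type = type, statistic = ct["g", 3],
                 p = ct["g", 4], note = "")
    } else {
      tab <- table(x, factor(g, levels = 0:2))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(covariate = v, type = type,
                 statistic = unname(tst$statistic), p = tst$p.value,
                 note = "")
    }
  })
  if (length(rows) == 0)
    return(data.frame(covariate = character(0), type = character(0),
                      statistic = numeric(0), p = numeric(0),
                      note = character(0)))
  do.call(rbind, rows)
}
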