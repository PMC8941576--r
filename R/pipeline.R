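#' @title End-to-end pipeline and reporting
#' @description
#' Orchestrates the stages — simulate (or load), exclude, associate,
#' progression markers, instrument validation, MR triangulation — under a
#' seeded configuration, emitting tidy CSV tables mirroring the study's
#' table layout plus a machine-readable JSON summary that contains every
#' reported number.
#' @name cli_reporting
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param simulate when TRUE, generate the cohort from `sim`; otherwise
#'   `cohort_csv` and `genotype_file` must exist.
#' @param sim a [simulation_config()] (simulate mode).
#' @param cohort_csv,genotype_file input paths (non-simulate mode);
#'   genotype files ending in `.vcf` go through [read_genotypes_vcf()].
#' @param seed integer seed recorded in the run log; in simulate mode it
#'   overrides `sim$seed`.
#' @param propagation `"fixed_expected"` or `"delta_method"` for the MR
#'   comparison.
#' @param bmi_cutoff,ast_uln cutoff overrides.
#' @param verbose logical; per-stage progress messages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE,
                            sim = simulation_config(),
                            cohort_csv = NULL, genotype_file = NULL,
                            seed = NULL,
                            propagation = c("fixed_expected", "delta_method"),
                            bmi_cutoff = 24, ast_uln = 40,
                            verbose = FALSE) {
  propagation <- match.arg(propagation)
  if (!simulate) {
    for (p in c(cohort_csv, genotype_file)) {
      if (is.null(p) || !file.exists(p))
        stopf("input file `%s` does not exist (non-simulate mode)",
              p %||% "<missing>", class = "suamr_invalid_parameter")
    }
  }
  if (!is.null(seed) && simulate) {
    sim$seed <- as.integer(seed)
  }
  structure(
    list(out_dir = out_dir, simulate = simulate, sim = sim,
         cohort_csv = cohort_csv, genotype_file = genotype_file,
         seed = if (is.null(seed)) sim$seed else as.integer(seed),
         propagation = propagation, bmi_cutoff = bmi_cutoff,
         ast_uln = ast_uln, verbose = verbose),
    class = "pipeline_config")
}

stage_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage `%s` failed: %s", name, conditionMessage(e),
          class = "suamr_stage_error"))
}

quartile_fit_rows <- function(qf, model, stratum) {
  df <- qf$estimates
  data.frame(stratum = stratum, model = model,
             quartile = df$quartile, or = df$estimate,
             ci_low = df$ci_low, ci_high = df$ci_high, p = df$p,
             trend_p = qf$trend_p, n = qf$n)
}

#' Run the full pipeline
#'
#' Sequences all stages and writes, under `out_dir`:
#' `exclusion_report.csv`, `descriptives_by_quartile.csv`,
#' `association_quartiles.csv` (all models and strata),
#' `progression_mean_differences.csv`, `progression_elevated.csv`,
#' `instruments.csv`, `mr_forest.csv`, and `summary.json` holding every
#' estimate the CSVs contain. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("`config` must be a pipeline_config", class = "suamr_invalid_parameter")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- stage: acquire data ---------------------------------------------------
  dat <- run_stage("load", {
    if (config$simulate) {
      stage_log(config, "simulating cohort (n = %d, scenario = %s, seed = %d)",
                config$sim$n, config$sim$scenario, config$sim$seed)
      generate_cohort(config$sim)
    } else {
      gt <- if (grepl("\\.vcf$", config$genotype_file)) {
        read_genotypes_vcf(config$genotype_file)
      } else {
        read_genotypes_csv(config$genotype_file)
      }
      list(cohort = read_cohort_csv(config$cohort_csv), genotypes = gt)
    }
  })

  # -- stage: exclusions -----------------------------------------------------
  excl <- run_stage("filter", apply_exclusions(dat$cohort))
  cohort <- excl$cohort
  stage_log(config, "exclusions: %d -> %d",
            attr(excl$report, "n_initial"), attr(excl$report, "n_final"))
  utils::write.csv(excl$report, file.path(config$out_dir, "exclusion_report.csv"),
                   row.names = FALSE)

  # -- stage: observational association -------------------------------------
  assoc <- run_stage("associate", {
    scheme <- compute_quartile_scheme(cohort)
    q <- assign_quartiles(cohort$sua, cohort$sex, scheme)
    desc <- do.call(rbind, lapply(1:4, function(k) {
      d <- cohort[q == k, ]
      data.frame(quartile = k, n = nrow(d), age = mean(d$age),
                 pct_female = 100 * mean(d$sex == "female"),
                 bmi = mean(d$bmi), sua = mean(d$sua),
                 pct_nafld = 100 * mean(d$nafld_followup))
    }))
    models <- c("univariate", "age_sex", "model1", "model2")
    total_rows <- do.call(rbind, lapply(models, function(m)
      quartile_fit_rows(
        fit_quartile_or(cohort, scheme = scheme, adjustment = adjustment_set(m)),
        m, "total")))
    strata_rows <- do.call(rbind, unlist(recursive = FALSE, lapply(
      c("sex", "bmi_category"), function(sv) {
        lapply(c("model1", "model2"), function(m) {
          res <- stratified_analysis(cohort, sv, fit_quartile_or,
                                     adjustment = adjustment_set(m),
                                     scheme = scheme,
                                     bmi_cutoff = config$bmi_cutoff)
          do.call(rbind, lapply(names(res), function(g)
            quartile_fit_rows(res[[g]], m, g)))
        })
      })))
    per_unit <- list(
      mgdl = fit_per_unit_or(cohort, adjustment = adjustment_set("model2")),
      umol = fit_per_unit_or(cohort, adjustment = adjustment_set("model2"),
                             unit = "umol_per_l"))
    list(scheme = scheme, descriptives = desc,
         quartile_rows = rbind(total_rows, strata_rows), per_unit = per_unit)
  })
  utils::write.csv(assoc$descriptives,
                   file.path(config$out_dir, "descriptives_by_quartile.csv"),
                   row.names = FALSE)
  utils::write.csv(assoc$quartile_rows,
                   file.path(config$out_dir, "association_quartiles.csv"),
                   row.names = FALSE)

  # -- stage: progression markers -------------------------------------------
  prog <- run_stage("progression", {
    nafld <- cohort[cohort$nafld_followup %in% TRUE, ]
    scheme_n <- compute_quartile_scheme(nafld)
    markers <- c("ALT", "GGT", "APRI", "FIB4")
    md <- do.call(rbind, lapply(markers, function(m) {
      d <- adjusted_mean_differences(nafld, m, scheme = scheme_n,
                                     ast_uln = config$ast_uln)
      d$marker <- m; d
    }))
    el <- lapply(markers, function(m)
      elevated_marker_or(nafld, m, scheme = scheme_n,
                         ast_uln = config$ast_uln,
                         bmi_cutoff = config$bmi_cutoff))
    names(el) <- markers
    list(nafld_n = nrow(nafld), scheme = scheme_n, mean_differences = md,
         elevated = el)
  })
  utils::write.csv(prog$mean_differences,
                   file.path(config$out_dir, "progression_mean_differences.csv"),
                   row.names = FALSE)
  el_csv <- do.call(rbind, lapply(names(prog$elevated), function(m) {
    e <- prog$elevated[[m]]
    qr <- quartile_fit_rows(e$quartile_fit, "adjusted", m)
    qr$percent_elevated <- unname(e$percent_elevated[paste0("Q", qr$quartile)])
    qr
  }))
  utils::write.csv(el_csv, file.path(config$out_dir, "progression_elevated.csv"),
                   row.names = FALSE)
  pu_csv <- do.call(rbind, lapply(names(prog$elevated), function(m) {
    e <- prog$elevated[[m]]
    rows <- c(list(all = e$per_mgdl), e$subgroups)
    do.call(rbind, lapply(names(rows), function(g) {
      d <- as.data.frame(rows[[g]]); d$subgroup <- g; d$marker <- m; d
    }))
  }))
  utils::write.csv(pu_csv, file.path(config$out_dir, "progression_per_mgdl.csv"),
                   row.names = FALSE)

  # -- stage: genetic instruments -------------------------------------------
  gen <- run_stage("genetics", {
    adj <- generator_adjustment()
    inst <- lapply(c("snp1", "snp2"), function(s)
      fit_instrument(cohort, dat$genotypes, s, adjustment = adj))
    names(inst) <- c("snp1", "snp2")
    gt <- dat$genotypes
    gt$score <- build_genetic_score(gt)
    merged <- merge(cohort, gt, by.x = "id", by.y = "participant_id")
    score_fit <- stats::lm(
      stats::reformulate(c("score", adj), response = "sua"),
      data = prepare_model_frame(merged))
    sct <- stats::coef(summary(score_fit))
    score_summary <- list(snp = "genetic_score", beta = sct["score", 1],
                          se = sct["score", 2], p = sct["score", 4])
    balance <- confounder_balance(
      cohort, dat$genotypes, "snp1",
      c(age = "continuous", bmi = "continuous", sua = "continuous",
        sex = "categorical", smoking = "categorical"))
    list(instruments = inst, score_summary = score_summary,
         merged = merged, balance = balance)
  })
  inst_csv <- do.call(rbind, lapply(gen$instruments, function(i)
    data.frame(snp = i$snp, beta = i$beta, se = i$se, p = i$p,
               variance_explained = i$variance_explained,
               hwe_p = i$hwe_p, call_rate = i$call_rate, n = i$n)))
  utils::write.csv(inst_csv, file.path(config$out_dir, "instruments.csv"),
                   row.names = FALSE)

  # -- stage: MR triangulation ----------------------------------------------
  mr <- run_stage("mr", {
    merged <- gen$merged
    adj <- generator_adjustment()
    or_bd <- assoc$per_unit$mgdl
    cmp <- lapply(c("snp1", "snp2", "score"), function(col) {
      summ <- if (col == "score") gen$score_summary else gen$instruments[[col]]
      obs <- observed_effect(merged, col, adjustment = adj)
      mr_compare(summ, or_bd, obs, mode = config$propagation)
    })
    names(cmp) <- c("snp1", "snp2", "score")
    cmp
  })
  forest <- do.call(rbind, lapply(mr, function(x)
    data.frame(instrument = x$instrument,
               observed_or = x$observed$estimate,
               observed_ci_low = x$observed$ci_low,
               observed_ci_high = x$observed$ci_high,
               expected_or = x$expected_or,
               expected_ci_low = x$expected_ci[1],
               expected_ci_high = x$expected_ci[2],
               p_difference = x$p)))
  utils::write.csv(forest, file.path(config$out_dir, "mr_forest.csv"),
                   row.names = FALSE)

  # -- summary ---------------------------------------------------------------
  summary_obj <- list(
    seed = config$seed,
    scenario = if (config$simulate) config$sim$scenario else "external",
    n_initial = attr(excl$report, "n_initial"),
    n_analyzed = attr(excl$report, "n_final"),
    n_incident_nafld = prog$nafld_n,
    exclusions = excl$report,
    quartile_cutoffs = assoc$scheme$cutoffs,
    descriptives = assoc$descriptives,
    association = assoc$quartile_rows,
    per_unit_or = list(mg_per_dl = as.data.frame(assoc$per_unit$mgdl),
                       umol_per_l = as.data.frame(assoc$per_unit$umol)),
    progression_mean_differences = prog$mean_differences,
    progression_elevated = el_csv,
    progression_per_mgdl = pu_csv,
    instruments = inst_csv,
    confounder_balance = gen$balance,
    mr = forest
  )
  jsonlite::write_json(summary_obj, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary_obj)
}
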