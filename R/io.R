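#' @title Cohort and genotype file I/O
#' @description
#' The shared CSV dialects (one header row, empty fields for missing
#' values), a column-mapping hook for externally produced cohort files,
#' a minimal VCF genotype importer, and the JSON pipeline/simulation
#' configuration reader.
#' @name io
NULL

#' Write a cohort table as CSV
#'
#' One header row; missing values as empty fields.
#'
#' @param cohort participant table.
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
}

#' Read a cohort table from CSV
#'
#' @param path input file.
#' @param column_map optional named character vector mapping file headers
#'   to canonical column names (`c(file_header = "canonical_name")`).
#' @return participant data frame with canonical columns; validated.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path))
    stopf("cohort file `%s` does not exist", path, class = "suamr_invalid_input")
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(column_map)) {
    hit <- names(d) %in% names(column_map)
    names(d)[hit] <- unname(column_map[names(d)[hit]])
  }
  for (v in c("physical_activity", "history_diabetes", "history_chd",
              "history_hypertension", "glucose_lowering_med",
              "sua_lowering_med", "nafld_assoc_med", "chronic_hepatitis",
              "cirrhosis", "hbsag_positive", "ultrasound_done_baseline",
              "ultrasound_done_followup", "nafld_baseline",
              "nafld_followup")) {
    if (v %in% names(d)) d[[v]] <- as.logical(d[[v]])
  }
  validate_cohort(d)
  d
}

#' Write genotypes as CSV
#'
#' Dialect: `participant_id,snp1,snp2` with allele counts.
#'
#' @param genotypes genotype table.
#' @param path output file.
#' @export
write_genotypes_csv <- function(genotypes, path) {
  utils::write.csv(genotypes, path, row.names = FALSE, na = "")
}

#' Read genotypes from CSV
#'
#' @param path input file with columns `participant_id,snp1,snp2`.
#' @return genotype data frame.
#' @export
read_genotypes_csv <- function(path) {
  if (!file.exists(path))
    stopf("genotype file `%s` does not exist", path, class = "suamr_invalid_input")
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("participant_id", "snp1", "snp2")
  if (!all(need %in% names(d)))
    stopf("genotype CSV must have columns %s", paste(need, collapse = ", "),
          class = "suamr_invalid_input")
  for (v in c("snp1", "snp2")) {
    if (!all(d[[v]] %in% c(0, 1, 2) | is.na(d[[v]])))
      stopf("`%s` contains values outside {0,1,2}", v,
            class = "suamr_invalid_input")
  }
  d
}

#' Minimal VCF genotype import
#'
#' Convenience reader for an uncompressed VCF carrying the two instrument
#' sites: extracts the GT subfield for the two named (or first two)
#' variant records, counting ALT alleles per diploid genotype;
#' phased and unphased separators are both accepted, and missing calls
#' (`./.`) give missing counts. Anything beyond this contract (multiple
#' ALTs, haploid calls, more sites) is rejected.
#'
#' @param path VCF file.
#' @param site_ids optional length-2 character vector of the variant IDs to
#'   use as snp1 and snp2, in that order; default: the first two records.
#' @return genotype data frame (`participant_id`, `snp1`, `snp2`) with one
#'   row per VCF sample.
#' @export
read_genotypes_vcf <- function(path, site_ids = NULL) {
  if (!file.exists(path))
    stopf("VCF file `%s` does not exist", path, class = "suamr_invalid_input")
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1)
    stopf("not a valid VCF: missing #CHROM header", class = "suamr_invalid_input")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10)
    stopf("VCF carries no sample columns", class = "suamr_invalid_input")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(recs, `[[`, character(1), 3)
  if (is.null(site_ids)) {
    if (length(recs) != 2)
      stopf("expected exactly 2 variant records, found %d; pass `site_ids`",
            length(recs), class = "suamr_invalid_input")
    site_ids <- ids
  }
  if (!all(site_ids %in% ids))
    stopf("site(s) %s absent from VCF",
          paste(setdiff(site_ids, ids), collapse = ", "),
          class = "suamr_invalid_input")
  count_alt <- function(rec) {
    alt <- rec[[5]]
    if (grepl(",", alt, fixed = TRUE))
      stopf("multiallelic site `%s` not supported", rec[[3]],
            class = "suamr_invalid_input")
    fmt <- strsplit(rec[[9]], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx))
      stopf("record `%s` lacks a GT field", rec[[3]],
            class = "suamr_invalid_input")
    vapply(rec[-(1:9)], function(smp) {
      gt <- strsplit(smp, ":", fixed = TRUE)[[1]][gt_idx]
      alleles <- strsplit(gt, "[/|]")[[1]]
      if (length(alleles) != 2)
        stopf("non-diploid genotype `%s`", gt, class = "suamr_invalid_input")
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }, numeric(1), USE.NAMES = FALSE)
  }
  g1 <- count_alt(recs[[match(site_ids[1], ids)]])
  g2 <- count_alt(recs[[match(site_ids[2], ids)]])
  data.frame(participant_id = samples, snp1 = g1, snp2 = g2,
             stringsAsFactors = FALSE)
}

#' Read a simulation configuration from JSON
#'
#' Every [simulation_config()] field is addressable by its argument name;
#' `confounder_effects` entries are named two-element objects with `sua`
#' and `logodds` components.
#'
#' @param path JSON file.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path))
    stopf("config file `%s` does not exist", path, class = "suamr_invalid_input")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$confounder_effects)) {
    raw$confounder_effects <- lapply(raw$confounder_effects, function(e)
      c(sua = e[["sua"]], logodds = e[["logodds"]]))
  }
  known <- names(formals(simulation_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stopf("unknown config fields: %s", paste(bad, collapse = ", "),
          class = "suamr_invalid_parameter")
  do.call(simulation_config, raw)
}
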