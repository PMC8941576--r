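test_that("HWE chi-square matches the closed form", {
  res <- hwe_test(c(0, 100, 0))
  expect_equal(res$chisq, 100)  # expected 25/50/25
  res2 <- hwe_test(c(25, 50, 25))
  expect_equal(res2$chisq, 0)
  expect_equal(res2$p, 1)
  expect_error(hwe_test(c(0, 0, 0)), class = "suamr_invalid_input")
  # oracle: chisq.test against HWE-expected proportions, fixed frequency
  counts <- c(180, 240, 95)
  q <- (counts[2] + 2 * counts[3]) / (2 * sum(counts))
  expected <- sum(counts) * c((1 - q)^2, 2 * q * (1 - q), q^2)
  expect_equal(hwe_test(counts)$chisq,
               sum((counts - expected)^2 / expected))
})

test_that("genotype coding models satisfy their identities", {
  g <- c(0, 1, 2, NA, 1)
  expect_equal(code_genotypes(g, "additive"), c(0, 1, 2, NA, 1))
  expect_equal(code_genotypes(g, "dominant"), c(0, 1, 1, NA, 1))
  cod <- code_genotypes(g, "codominant")
  expect_equal(cod[2, ], c(het = 1, hom_rare = 0))
  expect_equal(cod[3, ], c(het = 0, hom_rare = 1))
  # additive = het + 2*hom_rare
  expect_equal(code_genotypes(g, "additive"),
               unname(cod[, "het"] + 2 * cod[, "hom_rare"]))
  expect_error(code_genotypes(c(0, 3)), class = "suamr_invalid_input")
})

test_that("instrument fit recovers the generating betas and diagnostics", {
  dat <- generate_cohort(simulation_config(n = 8429, seed = 10))
  i1 <- fit_instrument(dat$cohort, dat$genotypes, "snp1",
                       adjustment = generator_adjustment())
  i2 <- fit_instrument(dat$cohort, dat$genotypes, "snp2",
                       adjustment = generator_adjustment())
  expect_lt(abs(i1$beta - 0.19), 2 * i1$se)
  expect_lt(abs(i2$beta - 0.22), 2 * i2$se)
  for (i in list(i1, i2)) {
    expect_gte(i$variance_explained, 0.005)
    expect_lte(i$variance_explained, 0.02)
    expect_equal(i$call_rate, 1)
    expect_gt(i$hwe_p, 1e-4)
  }
  # unadjusted option is plain R^2
  iu <- fit_instrument(dat$cohort, dat$genotypes, "snp1",
                       variance_explained = "unadjusted")
  expect_gt(iu$variance_explained, 0)
})

test_that("no-covariate binary-coded genotype beta equals the group-mean difference", {
  set.seed(44)
  n <- 800
  g <- sample(0:1, n, TRUE)
  cohort <- clean_cohort(n, seed = 44)
  cohort$sua <- 4 + 0.5 * g + stats::rnorm(n)
  gt <- data.frame(participant_id = cohort$id, snp1 = g, snp2 = 0L)
  inst <- fit_instrument(cohort, gt, "snp1")
  expect_equal(inst$beta,
               mean(cohort$sua[g == 1]) - mean(cohort$sua[g == 0]),
               tolerance = 1e-9)
})

test_that("permuted genotypes break the instrument", {
  dat <- generate_cohort(simulation_config(n = 6000, seed = 13))
  gt <- dat$genotypes
  set.seed(1)
  gt$snp1 <- sample(gt$snp1)
  inst <- fit_instrument(dat$cohort, gt, "snp1")
  expect_lt(abs(inst$beta), 3 * inst$se)
  expect_lt(inst$variance_explained, 0.002)
})

test_that("monomorphic SNPs are rejected", {
  cohort <- clean_cohort(20)
  gt <- data.frame(participant_id = cohort$id, snp1 = 1L, snp2 = 0L)
  expect_error(fit_instrument(cohort, gt, "snp1"),
               class = "suamr_degenerate_instrument")
})

test_that("genetic score sums risk alleles, propagates missingness, tracks SUA", {
  gt <- data.frame(participant_id = c("a", "b", "c"),
                   snp1 = c(1L, 0L, NA), snp2 = c(2L, 0L, 1L))
  expect_equal(build_genetic_score(gt), c(3L, 0L, NA))
  dat <- generate_cohort(simulation_config(n = 8429, seed = 19))
  score <- build_genetic_score(dat$genotypes)
  means <- tapply(dat$cohort$sua, score, mean)
  expect_true(all(diff(means[c("0", "1", "2", "3")]) > 0))
})

test_that("confounder balance: null covariates pass, planted signal fails", {
  dat <- generate_cohort(simulation_config(n = 8429, seed = 23))
  bal <- confounder_balance(dat$cohort, dat$genotypes, "snp1",
                            c(age = "continuous", bmi = "continuous",
                              smoking = "categorical", sex = "categorical"))
  expect_equal(nrow(bal), 4)
  expect_true(all(bal$p > 0.001))
  planted <- dat$cohort
  planted$fake <- dat$genotypes$snp1 * 2 + stats::rnorm(nrow(planted), 0, 0.1)
  bal2 <- confounder_balance(planted, dat$genotypes, "snp1",
                             c(fake = "continuous"))
  expect_lt(bal2$p, 1e-10)
  expect_equal(nrow(confounder_balance(dat$cohort, dat$genotypes, "snp1",
                                       c())), 0)
  const <- dat$cohort; const$one <- 1
  expect_warning(
    bal3 <- confounder_balance(const, dat$genotypes, "snp1",
                               c(one = "continuous")),
    "constant")
  expect_equal(bal3$note, "constant; skipped")
})

test_that("minimal VCF import matches the CSV dialect", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", "P3"), collapse = "\t"),
    paste(c("4", "9922167", "rs11722228", "C", "T", ".", "PASS", ".",
            "GT", "0/1", "1|1", "./."), collapse = "\t"),
    paste(c("4", "89052323", "rs2231142", "G", "T", ".", "PASS", ".",
            "GT:DP", "0/0:12", "0/1:9", "1/1:22"), collapse = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gt <- read_genotypes_vcf(f)
  expect_equal(gt$participant_id, c("P1", "P2", "P3"))
  expect_equal(gt$snp1, c(1, 2, NA))
  expect_equal(gt$snp2, c(0, 1, 2))
  gt2 <- read_genotypes_vcf(f, site_ids = c("rs2231142", "rs11722228"))
  expect_equal(gt2$snp1, c(0, 1, 2))
  unlink(f)
})
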