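test_that("se_from_ci and ci_from_se are mutual inverses", {
  se <- se_from_ci(0.90, 1.08)
  expect_equal(se, (log(1.08) - log(0.90)) / (2 * stats::qnorm(0.975)))
  expect_equal(se, 0.0465, tolerance = 1e-3)
  expect_equal(se_from_ci(1, 1), 0)
  set.seed(2)
  for (i in 1:20) {
    lo <- stats::runif(1, 0.5, 1); hi <- lo * exp(stats::runif(1, 0, 1))
    s <- se_from_ci(lo, hi)
    or <- exp((log(lo) + log(hi)) / 2)
    expect_equal(ci_from_se(or, s), c(lo, hi), tolerance = 1e-10)
  }
  expect_error(se_from_ci(-1, 2), class = "suamr_invalid_parameter")
  expect_error(se_from_ci(1.2, 1.1), class = "suamr_invalid_parameter")
})

test_that("expected effect is the product in log space", {
  e <- expected_effect(0.22, 1.18)
  expect_equal(e$log_odds, 0.22 * log(1.18))
  expect_equal(e$or, 1.037, tolerance = 5e-4)
  expect_equal(expected_effect(0, 17)$or, 1)
  # multiplicativity on the OR scale
  ba <- 0.13; bb <- 0.31; or <- 1.4
  expect_equal(expected_effect(ba + bb, or)$or,
               expected_effect(ba, or)$or * expected_effect(bb, or)$or,
               tolerance = 1e-12)
  expect_error(expected_effect(0.2, 0), class = "suamr_invalid_parameter")
})

test_that("Altman-Bland test: closed form, symmetry, degenerate guard", {
  res <- altman_bland_test(0.5, 0.1, 0.5, 0.3)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  r1 <- altman_bland_test(0.2, 0.1, -0.1, 0.15)
  r2 <- altman_bland_test(-0.1, 0.15, 0.2, 0.1)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$z, 0.3 / sqrt(0.1^2 + 0.15^2))
  expect_error(altman_bland_test(1, 0, 2, 0), class = "suamr_invalid_parameter")
})

test_that("AB p-values are uniform under matched truth (module-scale check)", {
  set.seed(5)
  nrep <- 500
  p <- replicate(nrep, {
    b <- 0.1; se1 <- 0.07; se2 <- 0.12
    altman_bland_test(stats::rnorm(1, b, se1), se1,
                      stats::rnorm(1, b, se2), se2)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("observed effect behaves under causal and broken instruments", {
  dat <- generate_cohort(simulation_config(n = 8429, seed = 28))
  merged <- dat$cohort
  merged$snp2 <- dat$genotypes$snp2
  obs <- observed_effect(merged, "snp2",
                         adjustment = generator_adjustment())
  # consistency of composition: near exp(0.22 * ln 1.18) ~ 1.037
  expect_lt(abs(obs$beta - 0.22 * log(1.18)), 3 * obs$se)
  set.seed(1)
  merged$perm <- sample(merged$snp2)
  obs_p <- observed_effect(merged, "perm",
                           adjustment = generator_adjustment())
  expect_lt(abs(obs_p$beta), 3 * obs_p$se)
  merged$const <- 1
  expect_error(observed_effect(merged, "const"),
               class = "suamr_degenerate_instrument")
})

test_that("mr_compare assembles expectation, modes and scale guards", {
  inst <- list(snp = "snp_test", beta = 0.22, se = 0.03)
  or_bd <- effect_estimate("per mg/dl", log(1.18), 0.026,
                           1.12, 1.24, 1e-10, 8429)
  obs <- effect_estimate("per allele", log(0.98), 0.0465,
                         0.90, 1.08, 0.66, 3887)
  cmp <- mr_compare(inst, or_bd, obs)
  expect_s3_class(cmp, "mr_comparison")
  expect_equal(cmp$expected_or, exp(0.22 * log(1.18)))
  expect_equal(cmp$expected_se, 0)
  expect_equal(cmp$expected_ci, rep(cmp$expected_or, 2))
  cmp_d <- mr_compare(inst, or_bd, obs, mode = "delta_method")
  expect_equal(cmp_d$expected_se, abs(log(1.18)) * 0.03)
  expect_gt(cmp_d$p, cmp$p)  # honest uncertainty can only widen
  # z sign flips when observed and expected swap roles
  expect_equal(sign(cmp$z), sign(obs$beta - cmp$expected_beta))
  bad <- effect_estimate("per umol/l", 0.003, 0.001, 1.001, 1.005, 0.01, 10)
  expect_error(mr_compare(inst, bad, obs),
               class = "suamr_invalid_combination")
  bad_obs <- effect_estimate("per mg/dl", 0.1, 0.05, 1.0, 1.22, 0.05, 10)
  expect_error(mr_compare(inst, or_bd, bad_obs),
               class = "suamr_invalid_combination")
})

test_that("zero-beta instrument reduces the comparison to a null test", {
  inst <- list(snp = "null_snp", beta = 0, se = 0.02)
  or_bd <- effect_estimate("per mg/dl", log(1.18), 0.026, 1.12, 1.24,
                           1e-10, 8429)
  obs <- effect_estimate("per allele", 0.05, 0.04,
                         exp(0.05 - 1.959964 * 0.04),
                         exp(0.05 + 1.959964 * 0.04), 0.21, 5000)
  cmp <- mr_compare(inst, or_bd, obs)
  expect_equal(cmp$expected_or, 1)
  expect_equal(cmp$z, 0.05 / 0.04)
})

test_that("power approximation: null boundary and monotonicity", {
  expect_equal(power_genetic(1000, 3000, 0.3, 1), 0.05)
  p_small <- power_genetic(500, 1500, 0.3, 1.1)
  p_big_n <- power_genetic(2000, 6000, 0.3, 1.1)
  p_big_or <- power_genetic(500, 1500, 0.3, 1.3)
  expect_gt(p_big_n, p_small)
  expect_gt(p_big_or, p_small)
  expect_error(power_genetic(0, 10, 0.3, 1.2),
               class = "suamr_invalid_parameter")
})
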