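test_that("quartile cutoffs use linear-interpolation percentiles per sex", {
  d <- data.frame(sex = rep(c("male", "female"), each = 8),
                  sua = c(1:8, 11:18))
  sch <- compute_quartile_scheme(d)
  expect_equal(sch$cutoffs$male, c(2.75, 4.5, 6.25))
  expect_equal(sch$cutoffs$female, c(12.75, 14.5, 16.25))
})

test_that("degenerate and undersized strata are rejected", {
  d <- data.frame(sex = rep(c("male", "female"), each = 8),
                  sua = c(rep(5, 8), 11:18))
  expect_error(compute_quartile_scheme(d), class = "suamr_insufficient_data")
  d2 <- data.frame(sex = c(rep("male", 3), rep("female", 8)),
                   sua = c(1:3, 11:18))
  expect_error(compute_quartile_scheme(d2), class = "suamr_insufficient_data")
})

test_that("assignment is left-closed; the printed male cutoffs place 5.0 in Q2", {
  sch <- quartile_scheme(male = c(4.47, 5.23, 6.10),
                         female = c(3.53, 4.15, 4.84))
  expect_equal(assign_quartiles(5.0, "male", sch), 2L)
  expect_equal(assign_quartiles(4.47, "male", sch), 2L)   # boundary goes up
  expect_equal(assign_quartiles(4.46, "male", sch), 1L)
  expect_equal(assign_quartiles(6.10, "male", sch), 4L)
  expect_equal(assign_quartiles(c(3.52, 3.53, 4.9), "female", sch),
               c(1L, 2L, 4L))
})

test_that("quartile group sizes differ by at most one for distinct values", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(40:200, 1)
    d <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                    sua = stats::runif(n))
    sch <- compute_quartile_scheme(d)
    q <- assign_quartiles(d$sua, d$sex, sch)
    for (s in c("male", "female")) {
      sizes <- tabulate(q[d$sex == s], 4)
      expect_lte(max(sizes) - min(sizes), 1)
    }
  }
})

test_that("unadjusted quartile OR equals the 2x2 cross-product ratio", {
  set.seed(21)
  for (rep in 1:10) {
    counts <- matrix(sample(5:40, 8, replace = TRUE), nrow = 4)
    # build a 4-quartile cohort directly via a scheme over known values
    d <- do.call(rbind, lapply(1:4, function(k) {
      data.frame(sua = k, case = rep(c(1, 0), times = counts[k, ]))
    }))
    d$sex <- "male"
    sch <- quartile_scheme(male = c(1.5, 2.5, 3.5), female = c(1.5, 2.5, 3.5))
    fit <- fit_quartile_or(d, outcome = "case", scheme = sch)
    for (k in 2:4) {
      or_cp <- cross_product_or(counts[k, 1], counts[k, 2],
                                counts[1, 1], counts[1, 2])
      expect_equal(fit$estimates$estimate[fit$estimates$quartile == k],
                   or_cp, tolerance = 1e-7)
    }
  }
})

test_that("null exposure gives ORs near 1; causal cohort gives monotone ORs", {
  set.seed(12)
  n <- 4000
  d <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                  sua = stats::rnorm(n, 5, 1),
                  case = stats::rbinom(n, 1, 0.3))
  sch <- compute_quartile_scheme(d)
  fit <- fit_quartile_or(d, outcome = "case", scheme = sch)
  expect_true(all(abs(log(fit$estimates$estimate)) <
                    3 * fit$estimates$se))
  expect_gt(fit$trend_p, 0.01)

  dat <- generate_cohort(simulation_config(n = 8429, seed = 2))
  sch2 <- compute_quartile_scheme(dat$cohort)
  fit2 <- fit_quartile_or(dat$cohort, scheme = sch2,
                          adjustment = adjustment_set("model1"))
  ors <- fit2$estimates$estimate[order(fit2$estimates$quartile)]
  expect_true(all(diff(c(1, ors)) > 0))
  expect_lt(fit2$trend_p, 0.001)
})

test_that("per-unit ORs satisfy the exact umol/mgdl exponent identity", {
  dat <- generate_cohort(simulation_config(n = 3000, seed = 6))
  or_mg <- fit_per_unit_or(dat$cohort, adjustment = adjustment_set("model1"))
  or_um <- fit_per_unit_or(dat$cohort, adjustment = adjustment_set("model1"),
                           unit = "umol_per_l")
  expect_equal(or_mg$estimate, or_um$estimate^59.5, tolerance = 1e-10)
  # the printed-value identity: OR_umol 1.003 -> OR_mgdl 1.003^59.5 ~ 1.195
  expect_equal(1.003^59.5, 1.1951, tolerance = 1e-4)
})

test_that("degenerate outcomes raise separation errors, not silent estimates", {
  d <- clean_cohort(30)
  d$nafld_followup <- TRUE
  sch <- quartile_scheme(male = c(4, 5, 6), female = c(3.5, 4.2, 4.9))
  expect_error(fit_quartile_or(d, scheme = sch),
               class = "suamr_separation_error")
  expect_error(fit_per_unit_or(d), class = "suamr_separation_error")
})

test_that("stratified analysis drops the stratification covariate and conserves n", {
  dat <- generate_cohort(simulation_config(n = 4000, seed = 9))
  res <- stratified_analysis(dat$cohort, "sex", fit_per_unit_or,
                             adjustment = adjustment_set("model1"))
  expect_named(res, c("female", "male"))
  pooled <- fit_per_unit_or(dat$cohort, adjustment = adjustment_set("model1"))
  for (r in res) {
    expect_lt(abs(r$beta - pooled$beta),
              2 * sqrt(r$se^2 + pooled$se^2) + 1e-9)
  }
  res_bmi <- stratified_analysis(dat$cohort, "bmi_category", fit_quartile_or,
                                 adjustment = adjustment_set("model1"),
                                 scheme = compute_quartile_scheme(dat$cohort))
  expect_equal(sum(vapply(res_bmi, function(x) x$n, numeric(1))),
               nrow(dat$cohort))
})

test_that("adjustment sets are nested as documented", {
  expect_length(adjustment_set("univariate"), 0)
  expect_true(all(adjustment_set("age_sex") %in% adjustment_set("model1")))
  expect_true(all(adjustment_set("model1") %in% adjustment_set("model2")))
  expect_equal(adjustment_set(c("age", "custom_var")), c("age", "custom_var"))
})
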