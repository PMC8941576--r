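# Shared fixtures, built in code.

# A small clean participant table passing every exclusion criterion.
clean_cohort <- function(n = 10, seed = 123) {
  set.seed(seed)
  data.frame(
    id = sprintf("C%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = stats::runif(n, 50, 75),
    bmi = stats::runif(n, 19, 29),
    waist = stats::runif(n, 70, 95),
    smoking = rep(c("never", "current", "quit"), length.out = n),
    drinking = rep(c("never", "current"), length.out = n),
    physical_activity = rep(c(TRUE, FALSE), length.out = n),
    history_diabetes = FALSE, history_chd = FALSE,
    history_hypertension = FALSE,
    glucose_lowering_med = FALSE, sua_lowering_med = FALSE,
    nafld_assoc_med = FALSE, chronic_hepatitis = FALSE, cirrhosis = FALSE,
    hbsag_positive = FALSE,
    alcohol_gpw = stats::runif(n, 0, 100),
    sua = stats::runif(n, 3, 8), alt = stats::runif(n, 10, 40),
    ast = stats::runif(n, 15, 35), ggt = stats::runif(n, 10, 60),
    plt = stats::runif(n, 150, 300), fpg = stats::runif(n, 4.5, 7),
    cre = stats::runif(n, 55, 100), tg = stats::runif(n, 0.6, 2.5),
    tc = stats::runif(n, 4, 6.5), hdl = stats::runif(n, 1, 2),
    ldl = stats::runif(n, 2, 4),
    ultrasound_done_baseline = TRUE, ultrasound_done_followup = TRUE,
    nafld_baseline = FALSE,
    nafld_followup = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE
  )
}

# Expand a 2x2 count table (exposed/unexposed x case/control) to records
# and return the closed-form cross-product odds ratio ad/bc.
expand_2x2 <- function(a, b, c_, d) {
  # a: exposed cases, b: exposed controls, c_: unexposed cases, d: unexposed controls
  data.frame(
    exposed = rep(c(1, 1, 0, 0), times = c(a, b, c_, d)),
    case = rep(c(1, 0, 1, 0), times = c(a, b, c_, d))
  )
}

cross_product_or <- function(a, b, c_, d) (a * d) / (b * c_)
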