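Package: suamr
Title: One-Sample Mendelian Randomization of Serum Uric Acid and Fatty Liver
Version: 0.1.0
Authors@R:
    person("Cohort", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-wave cohort analysis of serum uric acid (SUA)
    and incident nonalcoholic fatty liver disease (NAFLD): participant
    exclusion cascades, sex-specific quartile logistic models, hepatic
    necroinflammation and estimated-fibrosis scoring (APRI, FIB-4),
    genetic-instrument validation for two urate-transporter SNPs, and a
    one-sample Mendelian randomization triangulation that compares observed
    per-allele effects on NAFLD against the expected effect composed from
    the gene-exposure and exposure-outcome estimates, using the
    Altman-Bland interaction test. Includes a seeded synthetic-cohort
    generator with causal and marker (pure-confounding) scenarios so the
    whole pipeline is testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
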