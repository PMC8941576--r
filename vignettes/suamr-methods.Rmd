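---
title: "Methods: association and Mendelian randomization triangulation for serum uric acid and fatty liver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association and Mendelian randomization triangulation for serum uric acid and fatty liver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Elevated serum uric acid (SUA) is consistently associated with incident
nonalcoholic fatty liver disease (NAFLD) in observational cohorts, but an
association of this kind cannot distinguish a causal exposure from a
marker of a shared metabolic phenotype. `suamr` implements both halves of
the argument on a two-wave cohort design:

1. **Observational models.** Sex-specific SUA quartiles, logistic
   regression of incident NAFLD on quartile indicators under nested
   adjustment sets, per-unit odds ratios, and, among incident cases,
   covariance-adjusted differences in hepatic necroinflammation markers
   (ALT, GGT) and estimated-fibrosis scores (APRI, FIB-4).
2. **One-sample Mendelian randomization (MR).** Two urate-transporter
   SNPs (mapping to *SLC2A9* and *ABCG2*) serve as instruments. The
   per-allele effect on SUA, $\beta_{GB}$ (mg/dl per allele), and the
   exposure-outcome effect, $OR_{BD}$ (per mg/dl), compose the *expected*
   per-allele effect on NAFLD,
   $$\beta_E = \beta_{GB} \times \ln OR_{BD},$$
   which is compared with the *observed* per-allele logistic estimate via
   the Altman–Bland interaction test
   $$z = \frac{b_1 - b_2}{\sqrt{se_1^2 + se_2^2}}.$$
   Agreement of observed with expected supports causality; an observed
   effect near the null while the expected effect is positive supports
   the marker interpretation.

The MR logic rests on the usual instrumental-variable assumptions:
genotypes associate with SUA (checked by `fit_instrument()`), are
independent of confounders (checked by `confounder_balance()`), and
affect NAFLD only through SUA (not testable; probed qualitatively by the
two scenarios of the generator).

## The synthetic world

No individual-level data accompany the analysis, so the package carries a
seeded generator (`generate_cohort()`) whose defaults *are* the stated
world of the analysis, chosen once and not revisited:

* **Sample sizes.** Default n = 8429 (the analyzed cohort); the genotyped
  subset in the original design was n = 3887, used as such in the
  recovery tests. Marginal incident-NAFLD proportion 0.238 (2007/8429).
* **Genetics.** Two SNPs drawn in Hardy–Weinberg proportions with
  per-allele SUA effects 0.19 and 0.22 mg/dl. Risk-allele frequencies are
  not reported in the source; defaults 0.44 and 0.29 are plausible
  East-Asian values and are fully configurable.
* **SUA.** Sex-specific means 5.35 (men) and 4.25 (women) mg/dl, chosen
  to sit near the printed sex-specific quartile cutoffs, with residual
  noise SD 1.30 mg/dl. With the default frequencies this puts each SNP's
  variance explained near 1% (the source reports 1.06% and 1.09%),
  bracketed by the test band 0.5%–2%. A floor of 0.5 mg/dl keeps values
  physiologic after noise.
* **Confounders.** Age ≈ N(61.7, 7.8²), BMI ≈ N(23.3, 2.8²), 56% women,
  smoking/drinking/physical-activity and comorbidity marginals matching
  the descriptive table of the source; drawn independently (the source
  gives no joint structure). Each confounder carries a small effect on
  SUA and on the NAFLD log-odds (`default_confounder_effects()`).
  Drinkers' weekly alcohol is capped at the study's exclusion limit so
  the default cohort is analysis-ready at the configured n; the
  exclusion cascade is exercised through the optional `exclusion_rates`
  block instead.
* **Scenarios.** Under `causal`, NAFLD log-odds include
  $\ln(1.18) \times \mathrm{SUA}$, the fully adjusted per-mg/dl OR of the
  source. Under `marker`, the direct SUA coefficient is exactly zero and
  a latent confounder U ~ N(0, 1) raises both SUA (0.8 mg/dl per SD) and
  the NAFLD log-odds (0.5 per SD). Those two latent effects were chosen
  once so that the *induced* observational per-mg/dl OR is approximately
  `exp(0.5 × 0.8 / Var(SUA)) ≈ 1.18` — the marker world reproduces the
  printed observational association while carrying no causal path. The
  marker scenario models confounding, not reverse causation, which is
  out of scope.
* **Markers.** ALT, AST and GGT are log-normal with means shifted upward
  by NAFLD status and by SUA (log-scale slopes 0.09, 0.03 and 0.15 per
  mg/dl, sized so the quartile gradients have the order of magnitude of
  the printed adjusted mean differences); platelets are truncated normal,
  shifted slightly down with NAFLD and SUA so APRI and FIB-4 rise with
  both. The outcome intercept is solved by `uniroot` so the marginal
  incidence matches the configured prevalence; this calibration affects
  no slope coefficient.

**What a green test establishes — and does not.** The generator draws
confounders independently, uses exact logistic and log-linear links, and
contains no measurement error, no missingness (unless configured), no
longitudinal drop-out, and no genotyping error. Passing parameter
recovery therefore shows the estimators are correct under the model they
assume, not that the original study's estimates are right; the
dissociation test shows the MR contrast *can* separate the two worlds at
this sample size, not that it did so in the real cohort.

## Numerical and statistical choices

* **Quartiles.** Cutoffs are within-sex 25th/50th/75th percentiles with
  linear interpolation (R quantile type 7, the common convention; the
  source does not state its rule). Assignment is left-closed: a value
  equal to a cutoff goes to the higher quartile, matching the printed
  "≥" labels. Degenerate strata (fewer than 4 values, or ties making
  cutoffs non-increasing) raise errors rather than silently collapsing.
* **Trend test.** The ordinal quartile index 1–4 entered as a continuous
  covariate (standard epidemiological "P for trend"); within-quartile
  medians are available via `trend = "median"`. The source is silent on
  which it used.
* **Confidence intervals.** Wald intervals with z = 1.959964 internally;
  printed-value reproduction (the acceptance worked example) uses 1.96
  where the hand calculation does, via the explicit `z` argument of
  `se_from_ci()`.
* **Units.** SUA is mg/dl everywhere internally; µmol/l appears only at
  I/O boundaries with the source's own constant 59.5 (not the physical
  59.48), so printed conversions round-trip exactly. For one fit the two
  scales satisfy $OR_{mg/dl} = OR_{\mu mol/l}^{59.5}$ identically.
* **Separation and degeneracy.** A one-level outcome, a non-converged
  IRLS, or a separation warning accompanied by an absurd coefficient
  (|log-OR| > 10) raises a classed error naming the model; no silent
  huge odds ratios.
* **Missing data.** Complete-case per model, mirroring the source's
  removal of records with missing key fields.
* **Adjustment sets.** `univariate`, `age_sex`, `model1` (age, sex, BMI,
  smoking, drinking, physical activity) and `model2` (model1 plus CHD,
  hypertension, diabetes history and ALT, creatinine, fasting glucose)
  reproduce the source's nesting. Stratified analyses drop the
  stratification variable from the covariates. For the progression
  models the covariance (mean-difference) models omit age — the source's
  footnote omits it and its FIB-4 footnote is internally garbled, so the
  package's reading is: no age in any covariance model, and never age in
  a FIB-4 model since age is inside the score's formula; the elevated-
  marker OR models include age except for FIB-4. All sets are
  configurable and recorded in each result's metadata.
* **Parameter-recovery adjustment.** Recovery tests adjust for the
  generator's measured confounders (`generator_adjustment()`), which
  excludes ALT: in the generated world ALT is a *consequence* of NAFLD,
  so conditioning on it (as the source's model 2 does on real data)
  would bias a recovery check even though the source's choice may be
  reasonable for its own data.
* **Expected-effect uncertainty.** `mr_compare()` defaults to
  `fixed_expected` (expected SE = 0), reproducing the degenerate
  expected interval and the printed P = 0.25 of the source;
  `delta_method` propagates $|\ln OR_{BD}| \times se(\beta_{GB})$
  (the exposure-outcome estimate treated as fixed) for honest
  uncertainty, which can only enlarge the P value.
* **Power.** `power_genetic()` is a normal approximation
  ($se(\beta) \approx 1/\sqrt{N \cdot 2q(1-q) \cdot \phi(1-\phi)}$); the
  source's power method is unstated, so this is documented as
  approximate and is not an acceptance surface. It agrees with a
  simulation oracle within about one percentage point at the tested
  configuration and equals α exactly at OR = 1.
* **Other resolved ambiguities.** The univariate quartile model pools
  the sexes while keeping sex-specific quartile labels (the source's
  table reads that way); the AST upper limit of normal, unstated in the
  source, defaults to the conventional 40 U/l; BMI categories use the
  Chinese adult cutoff 24 kg/m²; exp(0.19 × ln 1.18) = 1.032 whereas the
  source prints 1.031 for the weaker SNP — presumably computed from
  unrounded inputs — so that three-decimal value is not asserted.

## Known limitations

* The generator's independence of confounders understates real-world
  collinearity (e.g. BMI with diabetes); adjusted and crude estimates
  differ less here than they would in real data.
* One-sample MR with two variants explaining ~2% of exposure variance is
  weakly powered for small effects; the package reproduces that honestly
  (the approximate power at the source's configuration is well below
  90%), and offers no multi-variant or two-sample estimators.
* The VCF importer covers exactly the two-site diploid GT contract and
  nothing more; real-world VCFs should be converted upstream.
* NAFLD enters as a binary ultrasound label; image criteria, assays and
  histology are out of scope.
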