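{
  "n": 8429,
  "seed": 1,
  "scenario": "marker",
  "maf_1": 0.44,
  "maf_2": 0.29,
  "beta_allele_1": 0.19,
  "beta_allele_2": 0.22,
  "baseline_prevalence": 0.238
}
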