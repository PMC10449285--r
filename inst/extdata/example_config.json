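{
  "sim": {
    "n_cohorts": 2,
    "n_per_cohort": 1000,
    "seed": 7
  },
  "mediators": ["TG", "HDL_C"],
  "n_boot": 200,
  "seed": 7
}
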