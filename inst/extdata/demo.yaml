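# Demo scenario: synthetic asthma / COPD / control sputum study at the
# published cell-fraction and RIN distributions, analyzed end to end.
seed: 17
n_per_group:
  asthma: 10
  copd: 10
  control: 10
n_features: 2000
noise_sd:
  expression: 25.0
  methylation: 0.02
confound_preservation: true
min_rin: 3
rin_correction: linear
majors:
  asthma: [AM, NG, EO]
  copd: [AM, NG]
  control: [AM, NG]
exclude: MO
bounds: auto
dmr_max_gap: 1000
dmr_min_cpgs: 2
enrich_p: 0.1
enrich_q: 0.2
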