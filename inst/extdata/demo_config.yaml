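# Demo pipeline configuration: simulate a small matched cohort pair and
# run the full comparison. Periods are the shipped defaults.
periods:
  pre:
    start: 2019-09-01
    end: 2019-12-31
  intra:
    start: 2020-03-01
    end: 2020-06-30
day_binning: calendar
timezone: UTC
simulate:
  presets:
    pre: pre_like
    intra: intra_like
  n_patients:
    pre: 50
    intra: 50
  seed: 7
weighted_eigenvector: false
alternative: two_sided
min_weight: 1
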