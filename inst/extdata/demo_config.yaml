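# Demo pipeline configuration: a small synthetic two-technique-style cohort
# (single technique here) analysed end to end in well under a minute.
seed: 11
simulate:
  n_patients: 5
  fractions_per_patient: [12, 12, 10, 9, 12]
  duration_s: 120
  sample_rate_hz: 4
  technique: SS-IMRT
summarize:
  bin_s: 1
estimate:
  estimators: [moment, reml]
  ci_level: 0.95
  compute_ci: true
margins:
  n_policy: max
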