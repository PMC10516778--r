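# Example run configuration for the ldlsim pipeline.
seed: 20390
output_dir: ldlsim_output
cohort:
  synthetic:
    n_patients: 2039
simulation:
  scenarios: [ACC_AHA_70, ESC_EAS_55, EXPLORATORY_40]
  n_replicates: 100
  shared_draws: false
  effect:
    rr_per_39: 0.78
    ci_low: 0.76
    ci_high: 0.80
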