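# SYNTHETIC REACH-like coefficient set (version 1).
#
# This is NOT a transcription of the published REACH next-cardiovascular-
# event model: those coefficients are published elsewhere and are not
# redistributed here. The file reproduces the structure of that equation
# (same covariates, log-hazard scale, baseline survival at 20 months) with
# plausible effect sizes from the secondary-prevention literature, and its
# baseline block is calibrated once so that the synthetic cohort shipped
# with this package has a 10-year risk distribution matching the reported
# marginals (median near 32% in the >= 70 mg/dl LDL-C stratum). Replace
# this file with a transcription of a published (re)calibration for real
# analyses; the engine validates any file with the same schema.
model: synthetic-reach-like
endpoint: recurrent cardiovascular event or cardiovascular death, 20 months
horizon_months: 20
baseline:
  form: survival
  value: 0.9378          # S0 at 20 months
  reference_score: 0.66  # linear predictor at which risk20 = 1 - S0
terms:
  - name: age
    coefficient: 0.022   # per year
    transform: {type: linear, center: 68}
  - name: sex
    coefficient: 0.13
    transform:
      type: factor
      codes: {female: 0, male: 1}
  - name: smoking
    coefficient: 1.0
    transform:
      type: factor
      codes: {non: 0.0, ex: 0.08, light: 0.25, moderate: 0.35, heavy: 0.45}
  - name: diabetes
    coefficient: 0.36
    transform: {type: binary}
  - name: hypertension
    coefficient: 0.10
    transform: {type: binary}
  - name: chf
    coefficient: 0.55
    transform: {type: binary}
  - name: af
    coefficient: 0.25
    transform: {type: binary}
  - name: sbp
    coefficient: 0.06    # per 10 mmHg
    transform: {type: linear, center: 135, scale: 10}
  - name: bmi
    coefficient: -0.005  # per kg/m^2
    transform: {type: linear, center: 28}
  - name: ckd_ge3
    coefficient: 0.30
    transform: {type: binary}
  - name: n_vascular_beds
    coefficient: 0.28    # per additional affected bed
    transform: {type: linear, center: 1}
  - name: event_within_1y
    coefficient: 0.45
    transform: {type: binary}
  - name: region
    coefficient: 0.0
    transform:
      type: factor
      codes: {europe: 0}
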