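---
title: "Simulating residual cardiovascular risk under LDL-C treatment goals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating residual cardiovascular risk under LDL-C treatment goals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlsim)
```

## The question the package answers

Patients with established atherosclerotic cardiovascular disease (ASCVD)
remain at high risk of further events even on lipid-lowering therapy
(LLT), and guidelines disagree on how far LDL cholesterol should be
pushed: the 2018 ACC/AHA recommendation uses 70 mg/dl as the threshold to
intensify therapy, while the 2019 ESC/EAS goal is below 55 mg/dl. `ldlsim`
quantifies, patient by patient, what closing that gap would buy: the LDL-C
reduction each patient needs, the relative risk reduction (RRR) that
reduction implies under the meta-analytic dose–response, the absolute risk
reduction (ARR) against the patient's own predicted baseline risk, and the
10-year risk that would *remain* — the residual risk.

The simulation is deliberately conservative about attainment: reaching the
"< 70" recommendation is modelled as achieving exactly 69 mg/dl, "< 55" as
54 mg/dl, and an exploratory "< 40" as 39 mg/dl, rather than any deeper
reduction a clinician might actually land on.

## Model and procedure

For each patient with baseline LDL-C $x \ge 70$ mg/dl and achieved level
$g \in \{69, 54, 39\}$:

1. **Gap.** Absolute reduction $\Delta = x - g$ and relative reduction
   $\Delta / x$.
2. **Baseline risk.** A REACH-style equation gives the 20-month risk of a
   recurrent cardiovascular event,
   $p_{20} = 1 - S_0^{\exp(\eta - \eta_0)}$, with linear predictor $\eta$
   over demographics and history, baseline survival $S_0$ and reference
   score $\eta_0$. The 10-year risk assumes a constant event rate
   (exponential survival): $p_{120} = 1 - (1 - p_{20})^{120/20}$.
3. **Effect model.** The rate ratio per 39 mg/dl (1.0 mmol/l) LDL-C
   reduction, $RR$, is drawn from a lognormal matched to the
   meta-analytic point estimate and 95% CI (default 0.78, 0.76–0.80;
   $\sigma_{\log} = (\ln 0.80 - \ln 0.76)/(2 \times 1.959964)$). The
   patient's RRR scales log-linearly:
   $RRR = 1 - RR^{\Delta/39}$, so a 39 mg/dl reduction at $RR = 0.78$
   gives exactly the canonical 22%.
4. **Absolute effect.** $ARR = p_{120} \times RRR$ and residual risk
   $p_{120} - ARR$; conservation ($ARR + \text{residual} = p_{120}$) holds
   row-wise by construction and is asserted in the tests.

Summaries are medians with interquartile ranges (IQR), the convention for
skewed clinical variables, stratified by the overall cohort and by the
three vascular-bed subtypes (coronary, cerebrovascular, peripheral artery
disease — CAD/CBD/PAD). Patients already below 70 mg/dl are not simulated;
their untreated baseline risk is summarized separately
(`residual_risk_below_70()`).

### Interpreting "randomly sampling from the inverse probability distribution"

The effect-model sampling is specified loosely in the source literature;
we interpret it as inverse-CDF sampling of a lognormal matched to the
point estimate and CI. Both the distribution family and the CI are
configuration, not code, and the degenerate `log_sd = 0` limit reproduces
every headline median analytically — a useful oracle that the Monte-Carlo
machinery adds no bias. Likewise it is unstated whether one draw is taken
per patient or per cohort replicate; the default is one independent draw
per patient per replicate, with `shared_draws = TRUE` available as a
sensitivity mode (one draw shared by all patients within a replicate).
With 100 replicates the two modes give indistinguishable pooled medians;
the shared mode widens between-replicate spread.

## The synthetic cohort generator

No patient-level data accompany the published summaries, so the package
ships a seeded generator (`generate_cohort()` + `default_cohort_spec()`)
that emulates the printed marginals of the 2039-patient European
secondary-prevention cohort the defaults are calibrated to:

* **Strata.** 61% of patients in the LDL-C $\ge 70$ stratum; subtype mix
  CAD:CBD:PAD of 470:751:818 overall, with the published per-stratum
  conditional mix.
* **LDL-C.** Published tables give only median (IQR) per stratum — 93
  (81–115) mg/dl above 70, 56 (46–63) below. A two-parameter lognormal
  cannot match an asymmetric quartile triple exactly; a *shifted*
  (three-parameter) lognormal can, in closed form
  (`fit_shifted_lognormal()`): shift
  $s = (m^2 - q_1 q_3)/(2m - q_1 - q_3)$, $\mu = \ln(m - s)$,
  $\sigma = \ln((q_3 - s)/(m - s))/z_{0.75}$. The 93 (81–115) triple is
  right-skewed and fits directly ($s = 66.6$); the 56 (46–63) triple is
  *left*-skewed, outside the reach of a positively skewed lognormal, so
  the family is extended with a reflected branch (fit the mirrored triple
  and negate). An exactly symmetric triple degenerates to a normal
  distribution matched to the same quartiles (with a warning). The
  $\ge 70$ stratum is truncated from below at 70 by rejection sampling
  (removing ~1% of mass, shifting quartiles by < 0.5 mg/dl); the below
  stratum is truncated to [20, 70) — the floor avoids implausible
  near-zero LDL-C.
* **Covariates.** Boolean covariates are Bernoulli at the published
  per-stratum prevalences (e.g. diabetes 50.7% below / 39.3% above 70);
  smoking is multinomial over five categories; age, SBP, DBP are normal
  at the published means/SDs, clipped to plausible physiological ranges;
  BMI uses its own quartile fit. Congestive heart failure, atrial
  fibrillation and a recent (< 1 year) event are risk-equation covariates
  whose prevalences are not in the published tables; the defaults
  (13%/14%/18%, both strata) were chosen once as typical of stable-ASCVD
  registries. Vascular-bed counts are multinomial with means matching the
  published per-bed involvement (~1.2 beds/patient).
* **LLT.** One regimen per patient drawn from the published
  combination-category frequencies per stratum, mapped to a
  representative regimen such that `classify_llt()` recovers the
  category.
* **Seeding.** One master seed expands into labelled substreams (stratum,
  subtype, LDL-C per stratum, each covariate, LLT), so adding a stream
  never perturbs existing ones and a cohort prefix is stable as `n`
  grows.

**What the generator does *not* emulate.** Covariates are independent
given stratum and subtype: the published tables contain marginals only,
so no correlation structure (e.g. LDL-C × diabetes beyond the stratum
split, or risk-factor clustering) is assumed. Quantities that depend only
on the LDL-C marginal — gaps, relative reductions, RRRs — are therefore
reproduced faithfully, while joint quantities (ARR and residual-risk
medians, which couple baseline risk to LDL-C) are structurally correct
but not expected to match published values exactly. Passing tests show
the pipeline arithmetic is right under the stated marginals; they do not
validate the independence assumption against real data.

## The risk-equation coefficients

The engine (`linear_predictor()`, `risk_20_months()`) is
coefficient-agnostic: terms, encodings and the baseline block live in a
validated YAML config, supporting both the baseline-survival and logistic
intercept parameterizations, because published recalibrations differ. The
packaged default, `reach_coefficients_file()`, is a **synthetic**
REACH-like set: it reproduces the structure of the published 20-month
next-cardiovascular-event equation (same covariates, log-hazard scale,
baseline survival at 20 months) with plausible secondary-prevention
effect sizes, and its baseline block ($S_0 = 0.9378$ at reference score
0.66) was calibrated once so the default synthetic cohort's 10-year risk
distribution matches the reported marginals (median near 32%,
IQR ≈ 25–43%, in the $\ge 70$ stratum). It is *not* a transcription of
the published coefficients, which are out of scope here; real analyses
should drop in a transcribed config, which the loader validates
unchanged. Tests run on toy coefficient sets with hand-computable
outputs, so nothing in the test suite depends on the synthetic defaults
except explicitly labelled soft calibration checks.

## Numerical conventions and edge cases

* Quartiles everywhere use linear interpolation between order statistics
  (position $1 + (n-1)p$; `stats::quantile()` type 7), fixed so golden
  outputs are byte-stable.
* Report percentages round half-away-from-zero to integers
  (`round_half_up()`), matching clinical presentation; raw fractions are
  retained in machine outputs.
* The stratum boundary is inclusive above: LDL-C exactly 70 belongs to
  the $\ge 70$ (simulated) stratum.
* The exponent denominator is 39 mg/dl exactly (the conventional
  1.0 mmol/l rounding), configurable via `rrr_for_reduction(per =)`.
* Horizon conversion is a semigroup (20 → 60 → 120 equals 20 → 120 to
  machine precision) and rejects `p = 1` when shortening horizons.
* Measured quantities are generated at clinical resolution (LDL-C, blood
  pressure, BMI to 0.1; age in whole years) so CSV round-trips are
  field-identical; missing or invalid covariates are rejected on read,
  never imputed — the underlying study restricted itself to patients with
  complete risk-equation data.
* `validate_cohort()` rejects regimens with no therapy at all (study
  inclusion required prescribed LLT); `classify_llt()` gives PCSK9i-
  containing combinations precedence over ezetimibe combinations, assigns
  ezetimibe plus moderate/high/unknown-intensity statin to the ezetimibe-
  combination category, and sends ezetimibe alone, ezetimibe with a
  low-intensity statin, PCSK9i monotherapy and unknown-intensity statin
  monotherapy to the residual category.

## Problem sizes

The default spec generates the full 2039-patient cohort in well under a
second. Distribution-level checks (quartile recovery, effect-distribution
quantiles, the headline gap/RRR medians) use $10^5$ draws, where sampling
error in a quartile is well under 0.2 mg/dl — an order of magnitude below
the ±1 mg/dl / ±1 percentage-point agreement asserted. Property tests use
cohorts of 300–1000 and a handful of Monte-Carlo replicates, which is
ample because the properties are exact (conservation, dominance,
transport) rather than statistical.

## A worked run

```{r, eval = FALSE}
cohort  <- generate_cohort(default_cohort_spec())
coeffs  <- read_reach_coefficients(reach_coefficients_file())
results <- simulate_goals(cohort, coeffs, n_replicates = 100, seed = 20390)
report  <- build_report(results, cohort)
subset(report, stratum == "overall" & quantity == "rrr")
```

The same pipeline is driven by a YAML config through `run_generate()`,
`run_simulate()` and `run_summarize()`, or from a shell via
`inst/cli/ldlsim.R`; every stage writes a provenance sidecar (config
hash, seed, package version) and is byte-reproducible under a fixed
config.

## Known limitations

* Independence of covariates given stratum (above) — joint quantities
  are illustrative.
* The constant-hazard 20-month → 10-year extrapolation ignores competing
  risks and any hazard decay; it under- or over-estimates uniformly
  across patients, which is acceptable for comparing goals, not for
  absolute calibration.
* No treatment-assignment modelling: the simulation asks what a
  reduction would buy, not which drug achieves it.
* The packaged coefficients are synthetic (see above); absolute risk
  levels carry no external validity until a transcribed coefficient
  config is supplied.
* No between-country heterogeneity; single `region` level by default.
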