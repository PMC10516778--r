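# Goal-gap and residual-risk Monte-Carlo simulation.
#
# For every patient with LDL-C >= 70 mg/dl the simulation computes the
# absolute and relative LDL-C reduction needed to reach a fixed achieved
# level (69 / 54 / 39 mg/dl: one below each guideline threshold, the
# conservative convention), scales a meta-analytic rate ratio per 39 mg/dl
# to the patient's own reduction, and converts the resulting relative risk
# reduction into an absolute risk reduction and residual 10-year risk
# against the patient's predicted baseline risk.

GOAL_SCENARIOS <- c(ACC_AHA_70 = 69, ESC_EAS_55 = 54, EXPLORATORY_40 = 39)

#' Treatment-goal scenario
#'
#' @param label One of `"ACC_AHA_70"` (achieved LDL-C 69 mg/dl),
#'   `"ESC_EAS_55"` (54 mg/dl) or `"EXPLORATORY_40"` (39 mg/dl).
#' @return A `"goal_scenario"` list with `label` and `achieved_ldl`.
#' @export
goal_scenario <- function(label) {
  label <- match.arg(label, names(GOAL_SCENARIOS))
  structure(list(label = label,
                 achieved_ldl = unname(GOAL_SCENARIOS[label])),
            class = "goal_scenario")
}

#' LDL-C effect-size distribution
#'
#' The rate ratio for cardiovascular events per 39 mg/dl (1.0 mmol/l)
#' LDL-C reduction, with meta-analytic uncertainty represented as a normal
#' distribution on the log scale:
#' `log_sd = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#' The default point estimate 0.78 corresponds to the canonical 22%
#' relative risk reduction per 1.0 mmol/l; the 95% CI defaults to
#' 0.76-0.80.
#'
#' @param rr_per_39 Point estimate of the rate ratio, in (0, 1).
#' @param ci_low,ci_high 95% confidence bounds,
#'   `0 < ci_low <= rr_per_39 <= ci_high < 1`.
#' @param log_sd Optional override of the derived log-scale SD (e.g. 0 for
#'   the deterministic limit).
#' @return An `"effect_distribution"` object.
#' @export
effect_distribution <- function(rr_per_39 = 0.78, ci_low = 0.76,
                                ci_high = 0.80, log_sd = NULL) {
  stopifnot(ci_low > 0, ci_low <= rr_per_39, rr_per_39 <= ci_high,
            ci_high < 1)
  log_sd <- log_sd %||% ((log(ci_high) - log(ci_low)) /
                           (2 * stats::qnorm(0.975)))
  structure(list(rr_per_39 = rr_per_39, ci_low = ci_low, ci_high = ci_high,
                 log_sd = log_sd),
            class = "effect_distribution")
}

#' Sample rate ratios from the effect distribution
#'
#' Inverse-CDF (lognormal) sampling around the meta-analytic point
#' estimate: draws are `exp(Normal(log(rr_per_39), log_sd))`.
#'
#' @param effect An [effect_distribution()].
#' @param n Number of draws.
#' @param seed Optional seed for reproducible draws.
#' @return Numeric vector of positive rate ratios.
#' @export
sample_rate_ratios <- function(effect, n, seed = NULL) {
  stopifnot(inherits(effect, "effect_distribution"), n >= 1)
  draw <- function()
    exp(stats::rnorm(n, log(effect$rr_per_39), effect$log_sd))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Required LDL-C reduction to reach a goal scenario
#'
#' @param ldl_c Baseline LDL-C in mg/dl; every value must be >= 70 (the
#'   simulation population).
#' @param scenario A [goal_scenario()].
#' @return A data.frame with `delta_ldl` (mg/dl, `ldl_c - achieved_ldl`)
#'   and `rel_reduction` (fraction of baseline, `delta_ldl / ldl_c`).
#' @export
#' @examples
#' required_reduction(93, goal_scenario("ACC_AHA_70"))  # delta 24
required_reduction <- function(ldl_c, scenario) {
  stopifnot(inherits(scenario, "goal_scenario"))
  if (any(ldl_c < 70))
    stop("required_reduction applies only to patients with LDL-C >= 70 mg/dl")
  delta <- ldl_c - scenario$achieved_ldl
  data.frame(delta_ldl = delta, rel_reduction = delta / ldl_c)
}

#' Relative risk reduction for a given LDL-C reduction
#'
#' Scales the rate ratio per 39 mg/dl to an arbitrary reduction under
#' log-linear dose-response: `rrr = 1 - rate_ratio^(delta_ldl / per)`.
#' At `delta_ldl = 39` and `rate_ratio = 0.78` this is exactly 0.22, the
#' canonical 22% relative risk reduction per 1.0 mmol/l.
#'
#' @param delta_ldl Absolute LDL-C reduction in mg/dl (>= 0).
#' @param rate_ratio Rate ratio per `per` mg/dl, in (0, 1).
#' @param per Scaling denominator in mg/dl (default 39, i.e. 1.0 mmol/l as
#'   conventionally rounded; configurable for sensitivity analysis).
#' @return Fraction in `[0, 1)`.
#' @export
rrr_for_reduction <- function(delta_ldl, rate_ratio, per = 39) {
  if (any(delta_ldl < 0)) stop("delta_ldl must be non-negative")
  if (any(rate_ratio <= 0 | rate_ratio >= 1))
    stop("rate_ratio must lie in (0, 1)")
  1 - rate_ratio ^ (delta_ldl / per)
}

#' Simulate a goal scenario over a cohort
#'
#' Restricts the cohort to LDL-C >= 70 mg/dl (reporting the excluded
#' count), predicts each patient's baseline 10-year risk, computes the
#' required reduction for the scenario, and for each of `n_replicates`
#' Monte-Carlo replicates draws a rate ratio per patient (or one shared
#' draw per replicate with `shared_draws = TRUE`), yielding per-row RRR,
#' ARR (`baseline * rrr`) and residual 10-year risk (`baseline - arr`).
#'
#' @param cohort A validated cohort data.frame.
#' @param coeffs A `"reach_coefficients"` object.
#' @param scenario A [goal_scenario()].
#' @param effect An [effect_distribution()].
#' @param n_replicates Monte-Carlo replicates (default 100).
#' @param seed Seed for the rate-ratio draws.
#' @param shared_draws If `TRUE`, all patients share one rate-ratio draw
#'   per replicate (sensitivity mode); default is one independent draw per
#'   patient per replicate.
#' @return A data.frame, one row per patient x replicate: `patient_id`,
#'   `scenario`, `replicate`, `baseline_p120`, `delta_ldl`,
#'   `rel_reduction`, `rate_ratio`, `rrr`, `arr`, `residual_p120`, with the
#'   excluded patient count in attribute `"n_excluded"`.
#' @export
simulate_scenario <- function(cohort, coeffs, scenario, effect,
                              n_replicates = 100, seed = 1,
                              shared_draws = FALSE) {
  stopifnot(inherits(scenario, "goal_scenario"),
            inherits(effect, "effect_distribution"), n_replicates >= 1)
  eligible <- cohort$ldl_c >= 70
  n_excluded <- sum(!eligible)
  if (!any(eligible))
    stop("no eligible patients (all LDL-C < 70 mg/dl)")
  sub <- cohort[eligible, , drop = FALSE]
  n <- nrow(sub)
  p120 <- predict_risk10(sub, coeffs)
  gap <- required_reduction(sub$ldl_c, scenario)
  n_draws <- if (shared_draws) n_replicates else n * n_replicates
  rr <- sample_rate_ratios(effect, n_draws,
                           seed = substream_seed(seed,
                                                 paste0("rr_", scenario$label)))
  if (shared_draws) rr <- rep(rr, each = n)
  out <- data.frame(
    patient_id = rep(sub$patient_id, times = n_replicates),
    scenario = scenario$label,
    replicate = rep(seq_len(n_replicates), each = n),
    baseline_p120 = rep(p120, times = n_replicates),
    delta_ldl = rep(gap$delta_ldl, times = n_replicates),
    rel_reduction = rep(gap$rel_reduction, times = n_replicates),
    rate_ratio = rr,
    stringsAsFactors = FALSE)
  out$rrr <- rrr_for_reduction(out$delta_ldl, out$rate_ratio)
  out$arr <- out$baseline_p120 * out$rrr
  out$residual_p120 <- out$baseline_p120 - out$arr
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Simulate several goal scenarios
#'
#' @inheritParams simulate_scenario
#' @param scenarios Character vector of scenario labels (default all
#'   three).
#' @return Row-bound results of [simulate_scenario()] for each scenario
#'   (each scenario gets its own rate-ratio substream).
#' @export
simulate_goals <- function(cohort, coeffs,
                           scenarios = names(GOAL_SCENARIOS),
                           effect = effect_distribution(),
                           n_replicates = 100, seed = 1,
                           shared_draws = FALSE) {
  parts <- lapply(scenarios, function(lab)
    simulate_scenario(cohort, coeffs, goal_scenario(lab), effect,
                      n_replicates = n_replicates, seed = seed,
                      shared_draws = shared_draws))
  out <- do.call(rbind, parts)
  attr(out, "n_excluded") <- attr(parts[[1]], "n_excluded")
  out
}

#' Residual risk of patients already below 70 mg/dl
#'
#' Median/IQR of predicted baseline 10-year risk among patients with
#' LDL-C < 70 mg/dl, with no simulated intervention.
#'
#' @inheritParams simulate_scenario
#' @return A [median_iqr()] summary of their 10-year risk.
#' @export
residual_risk_below_70 <- function(cohort, coeffs) {
  sub <- cohort[cohort$ldl_c < 70, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no patients with LDL-C < 70 mg/dl")
  median_iqr(predict_risk10(sub, coeffs))
}
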