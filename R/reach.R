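# REACH-style 20-month recurrent-event risk equation and constant-hazard
# horizon conversion.
#
# The engine is coefficient-agnostic: a coefficient object names each
# covariate, its log-hazard coefficient and an encoding rule, plus a
# baseline block (either baseline survival at the model's native horizon
# with a reference score, or a logistic intercept). Coefficients are loaded
# from a YAML config so unit tests can run on toy sets with hand-computable
# outputs, and published recalibrations can be swapped in without touching
# code. The packaged default (see `reach_coefficients_file()`) is a
# SYNTHETIC stand-in with the REACH covariate structure, calibrated to the
# risk marginals of the cohort the generator emulates; it is not a
# transcription of the published model.

#' Construct a risk-equation coefficient set
#'
#' @param terms A named list; each element is a list with `coefficient`
#'   (log-hazard scale) and `transform`, one of:
#'   * `list(type = "linear", center =, scale =)` — contribution is
#'     `coefficient * (x - center)/scale` (both optional; default 0/1);
#'   * `list(type = "binary")` — contribution is `coefficient * (x != 0)`;
#'   * `list(type = "factor", codes = c(level = code, ...))` — contribution
#'     is `coefficient * codes[x]`.
#' @param baseline A list: `form` (`"survival"` or `"intercept"`) and
#'   `value` (baseline survival in (0,1) at `horizon_months` for the
#'   survival form; the logistic intercept otherwise), plus
#'   `reference_score` (survival form only; linear-predictor value at which
#'   risk equals `1 - value`).
#' @param horizon_months Native prediction horizon of the equation
#'   (default 20).
#' @return A `"reach_coefficients"` object.
#' @export
reach_coefficients <- function(terms, baseline, horizon_months = 20) {
  stopifnot(is.list(terms), length(names(terms)) == length(terms))
  baseline$form <- match.arg(baseline$form, c("survival", "intercept"))
  if (baseline$form == "survival") {
    if (!(baseline$value > 0 && baseline$value < 1))
      stop("baseline survival must lie in (0, 1)")
    baseline$reference_score <- baseline$reference_score %||% 0
  }
  for (nm in names(terms)) {
    tr <- terms[[nm]]$transform
    if (is.null(tr$type) ||
        !tr$type %in% c("linear", "binary", "factor"))
      stop("term '", nm, "': transform type must be linear, binary or factor")
    if (tr$type == "factor" && is.null(tr$codes))
      stop("term '", nm, "': factor transform needs codes")
    if (is.null(terms[[nm]]$coefficient))
      stop("term '", nm, "': missing coefficient")
  }
  structure(list(terms = terms, baseline = baseline,
                 horizon_months = horizon_months),
            class = "reach_coefficients")
}

#' Load risk-equation coefficients from a YAML config
#'
#' @param path Path to a YAML file with a `baseline` block and a `terms`
#'   list (each entry: `name`, `coefficient`, `transform`). The schema is
#'   validated on load.
#' @return A `"reach_coefficients"` object.
#' @seealso [reach_coefficients_file()] for the packaged default.
#' @export
read_reach_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$baseline) || is.null(cfg$terms))
    stop("coefficient config must have 'baseline' and 'terms' blocks")
  terms <- list()
  for (term in cfg$terms) {
    if (is.null(term$name)) stop("every term needs a name")
    tr <- term$transform %||% list(type = "linear")
    if (identical(tr$type, "factor")) tr$codes <- unlist(tr$codes)
    terms[[term$name]] <- list(coefficient = term$coefficient,
                               transform = tr)
  }
  reach_coefficients(terms, cfg$baseline,
                     horizon_months = cfg$horizon_months %||% 20)
}

#' Path to the packaged synthetic default coefficient file
#'
#' The packaged default is a synthetic REACH-like coefficient set (see the
#' package vignette); the published equation's coefficients can be supplied
#' as a drop-in replacement config.
#'
#' @return File path.
#' @export
reach_coefficients_file <- function() {
  system.file("extdata", "reach_coefficients_synthetic.yaml",
              package = "ldlsim", mustWork = TRUE)
}

encode_term <- function(x, term, name) {
  tr <- term$transform
  switch(tr$type,
    linear = {
      if (!is.numeric(x)) stop("covariate '", name, "' must be numeric")
      (x - (tr$center %||% 0)) / (tr$scale %||% 1)
    },
    binary = as.numeric(as.logical(x)),
    factor = {
      codes <- tr$codes
      if (!all(x %in% names(codes)))
        stop("covariate '", name, "' has levels outside the transform codes")
      unname(codes[as.character(x)])
    })
}

#' Linear predictor of the risk equation
#'
#' Sum over terms of coefficient times encoded covariate, evaluated
#' row-wise on a cohort data.frame.
#'
#' @param cohort A validated cohort data.frame.
#' @param coeffs A `"reach_coefficients"` object.
#' @return Numeric vector, one score per patient.
#' @export
linear_predictor <- function(cohort, coeffs) {
  stopifnot(inherits(coeffs, "reach_coefficients"))
  score <- numeric(nrow(cohort))
  for (nm in names(coeffs$terms)) {
    if (!nm %in% names(cohort))
      stop("missing covariate required by the risk equation: ", nm)
    score <- score +
      coeffs$terms[[nm]]$coefficient *
        encode_term(cohort[[nm]], coeffs$terms[[nm]], nm)
  }
  score
}

#' 20-month event risk
#'
#' Survival form: `p = 1 - S0 ^ exp(score - reference_score)`; intercept
#' form: `p = plogis(intercept + score)`. Both are strictly increasing in
#' the score and map into (0, 1).
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of event probabilities over the equation's native
#'   horizon (20 months by default).
#' @export
risk_20_months <- function(cohort, coeffs) {
  score <- linear_predictor(cohort, coeffs)
  b <- coeffs$baseline
  if (b$form == "survival") {
    1 - b$value ^ exp(score - b$reference_score)
  } else {
    stats::plogis(b$value + score)
  }
}

#' Convert a cumulative risk between time horizons
#'
#' Under a constant event rate (exponential survival), a cumulative risk
#' `p_from` over `t_from` months implies hazard
#' `-log(1 - p_from) / t_from`, and hence risk
#' `1 - (1 - p_from)^(t_to / t_from)` over `t_to` months. The conversion is
#' a semigroup: composing 20 -> 60 -> 120 equals 20 -> 120.
#'
#' @param p_from Cumulative risk in `[0, 1)` (1 allowed only when
#'   `t_to >= t_from`).
#' @param t_from,t_to Strictly positive horizons in months.
#' @return Converted cumulative risk.
#' @export
#' @examples
#' convert_risk_horizon(0.10, 20, 120)  # 1 - 0.9^6
convert_risk_horizon <- function(p_from, t_from, t_to) {
  if (t_from <= 0 || t_to <= 0) stop("time horizons must be positive")
  if (any(p_from < 0 | p_from > 1)) stop("p_from must lie in [0, 1]")
  if (any(p_from == 1) && t_to < t_from)
    stop("cannot shorten the horizon of a certain event")
  1 - (1 - p_from) ^ (t_to / t_from)
}

#' Predicted 10-year cardiovascular risk
#'
#' Convenience wrapper: native-horizon risk from the equation, converted to
#' 120 months under the constant-hazard assumption.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of 10-year risks.
#' @export
predict_risk10 <- function(cohort, coeffs) {
  convert_risk_horizon(risk_20_months(cohort, coeffs),
                       coeffs$horizon_months, 120)
}
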