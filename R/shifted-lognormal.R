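# Three-parameter (shifted) lognormal calibrated to printed quartiles.
#
# Published cohort tables report LDL-C only as median (Q1-Q3). A two-parameter
# lognormal cannot reproduce an arbitrary asymmetric quartile triple exactly;
# a location shift adds the third degree of freedom, and the three quartile
# constraints then identify all three parameters in closed form.
#
# For a right-skewed triple (median - q1 < q3 - median):
#   X = shift + exp(N(log_median, log_sd))
#   shift      = (median^2 - q1*q3) / (2*median - q1 - q3)
#   log_median = ln(median - shift)
#   log_sd     = ln((q3 - shift)/(median - shift)) / z_{0.75}
# A left-skewed triple is fitted by mirroring (fit -q3, -median, -q1 and
# negate), giving X = shift - exp(N(log_median, log_sd)).
# An exactly symmetric triple is the degenerate (normal) limit of the family;
# it falls back to N(median, (q3 - median)/z_{0.75}) with a warning.

#' Fit a shifted lognormal to a quartile triple
#'
#' Returns the unique member of the shifted (possibly reflected) lognormal
#' family whose 25th/50th/75th percentiles equal `q1`/`median`/`q3` exactly.
#'
#' @param q1,median,q3 Quartiles, with `q1 < median < q3`. For LDL-C these are
#'   concentrations in mg/dl.
#' @return An object of class `"shifted_lognormal"`: a list with elements
#'   `family` (`"shifted_lognormal"` or `"normal"`), `shift`, `log_median`,
#'   `log_sd`, `reflected`, and (normal fallback only) `mean`, `sd`.
#' @details With a symmetric triple (`2*median == q1 + q3`) the lognormal
#'   shape parameter degenerates; the function warns and returns a normal
#'   distribution matched to the same quartiles.
#' @export
#' @examples
#' fit_shifted_lognormal(81, 93, 115)   # right-skewed, shift 66.6
#' fit_shifted_lognormal(46, 56, 63)    # left-skewed, reflected branch
fit_shifted_lognormal <- function(q1, median, q3) {
  stopifnot(is.numeric(q1), is.numeric(median), is.numeric(q3))
  if (!(q1 < median && median < q3))
    stop("quartiles must satisfy q1 < median < q3")
  z75 <- stats::qnorm(0.75)
  if (isTRUE(all.equal(2 * median, q1 + q3))) {
    warning("symmetric quartiles: falling back to a normal distribution")
    out <- list(family = "normal", mean = median, sd = (q3 - median) / z75,
                shift = NA_real_, log_median = NA_real_, log_sd = NA_real_,
                reflected = FALSE)
    class(out) <- "shifted_lognormal"
    return(out)
  }
  reflected <- (median - q1) > (q3 - median)
  if (reflected) {
    tmp <- c(-q3, -median, -q1)
    q1u <- tmp[1]; mu <- tmp[2]; q3u <- tmp[3]
  } else {
    q1u <- q1; mu <- median; q3u <- q3
  }
  shift <- (mu^2 - q1u * q3u) / (2 * mu - q1u - q3u)
  if (shift >= q1u)
    stop("infeasible quartile triple: fitted shift is not below q1")
  log_median <- log(mu - shift)
  log_sd <- log((q3u - shift) / (mu - shift)) / z75
  out <- list(family = "shifted_lognormal",
              shift = if (reflected) -shift else shift,
              log_median = log_median, log_sd = log_sd,
              reflected = reflected, mean = NA_real_, sd = NA_real_)
  class(out) <- "shifted_lognormal"
  out
}

#' Distribution functions for the fitted shifted lognormal
#'
#' `pshlnorm()`, `qshlnorm()` and `rshlnorm()` are the CDF, quantile function
#' and random generator for a fit returned by [fit_shifted_lognormal()]
#' (including its reflected and normal-fallback branches).
#'
#' @param x,p Numeric vectors of values / probabilities.
#' @param n Number of draws.
#' @param params A `"shifted_lognormal"` object.
#' @return Numeric vector.
#' @export
pshlnorm <- function(x, params) {
  stopifnot(inherits(params, "shifted_lognormal"))
  if (params$family == "normal")
    return(stats::pnorm(x, params$mean, params$sd))
  if (params$reflected) {
    # X = shift - LN  =>  P(X <= x) = P(LN >= shift - x)
    stats::plnorm(params$shift - x, params$log_median, params$log_sd,
                  lower.tail = FALSE)
  } else {
    stats::plnorm(x - params$shift, params$log_median, params$log_sd)
  }
}

#' @rdname pshlnorm
#' @export
qshlnorm <- function(p, params) {
  stopifnot(inherits(params, "shifted_lognormal"))
  if (params$family == "normal")
    return(stats::qnorm(p, params$mean, params$sd))
  if (params$reflected) {
    params$shift - stats::qlnorm(1 - p, params$log_median, params$log_sd)
  } else {
    params$shift + stats::qlnorm(p, params$log_median, params$log_sd)
  }
}

#' @rdname pshlnorm
#' @export
rshlnorm <- function(n, params) {
  stopifnot(inherits(params, "shifted_lognormal"))
  if (params$family == "normal")
    return(stats::rnorm(n, params$mean, params$sd))
  draws <- stats::rlnorm(n, params$log_median, params$log_sd)
  if (params$reflected) params$shift - draws else params$shift + draws
}

#' Sample LDL-C values from a fitted marginal, with optional truncation
#'
#' Draws from a [fit_shifted_lognormal()] fit by rejection sampling inside
#' `[lower, upper)`. Used to emulate the LDL-C strata of a cohort whose
#' published quartiles the fit reproduces (e.g. the >= 70 mg/dl stratum is
#' the fitted marginal truncated from below at 70).
#'
#' @param params A `"shifted_lognormal"` object.
#' @param n Number of draws (>= 1).
#' @param lower,upper Optional truncation bounds: draws satisfy
#'   `x >= lower` and `x < upper`.
#' @param seed Optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @details Errors if the truncation region holds less than 1e-3 of the
#'   distribution's mass (almost surely a mis-specified truncation).
#' @export
#' @examples
#' fit <- fit_shifted_lognormal(81, 93, 115)
#' x <- sample_ldl(fit, 1000, lower = 70, seed = 1)
#' stopifnot(all(x >= 70))
sample_ldl <- function(params, n, lower = NULL, upper = NULL, seed = NULL) {
  stopifnot(inherits(params, "shifted_lognormal"), n >= 1)
  lo <- lower %||% -Inf
  hi <- upper %||% Inf
  accept_mass <- pshlnorm(hi, params) - pshlnorm(lo, params)
  if (accept_mass < 1e-3)
    stop("truncation region holds < 1e-3 of the probability mass; ",
         "check the truncation bounds")
  draw <- function() {
    out <- numeric(0)
    while (length(out) < n) {
      m <- ceiling((n - length(out)) / accept_mass * 1.1) + 16
      x <- rshlnorm(m, params)
      out <- c(out, x[x >= lo & x < hi])
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
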