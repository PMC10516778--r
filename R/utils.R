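# Internal helpers shared across modules.

# Derive a reproducible substream seed from a master seed and a stream label.
# Streams are independent in the sense that adding a new label never perturbs
# draws made under existing labels. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master))
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for the integer percentages in the printed summaries
#' (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
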