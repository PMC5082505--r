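#' Derive a stream-specific random seed
#'
#' All randomness in the package is routed through integer seeds derived
#' deterministically from a single master seed, so that any run is a pure
#' function of (inputs, config, seed).
#'
#' @param seed master integer seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed, always in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Weyl-style mixing keeps distinct streams decorrelated without exceeding
  # the 32-bit range R requires of set.seed().
  s <- (abs(seed) * 69069 + stream * 362437 + 1) %% 2147483629
  as.integer(s)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's
#' `.Random.seed`, so library functions never perturb user-level randomness.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Convert a signed t statistic to a calibrated standard-normal deviate
#'
#' Two-tailed p from the t distribution at `df` effective degrees of freedom,
#' halved back to a signed one-tailed normal quantile. Computed on the log
#' scale so extreme statistics do not underflow.
#'
#' @param t t statistic (vectorized).
#' @param df effective degrees of freedom.
#' @return z, same sign as `t`.
#' @export
t_to_z <- function(t, df) {
  stopifnot(all(df > 0))
  lp <- stats::pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  sign(t) * z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
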