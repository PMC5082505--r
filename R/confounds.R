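# Nuisance side of the connectivity GLM: Volterra motion expansion,
# artifact signals, SVD reduction, discrete-cosine band-pass set.

#' Second-order, lag-five Volterra expansion of a motion index
#'
#' Builds the 90-regressor motion confound set: a first-order block of nine
#' columns — the displacement series at lags 0-4 plus the four successive
#' differences between consecutive lagged columns —
#' and a second-order block of all 81 ordered pairwise products of the nine.
#' This captures linear, delayed (spin-history) and quadratic
#' (movement-by-distortion) effects of motion. Lagged columns are padded at
#' the start with the initial displacement value, so series length is
#' preserved without introducing a spurious onset step (a constant
#' displacement yields identically zero difference columns).
#'
#' Column order is fixed: `lag0..lag4`, `diff1..diff4`
#' (`diffk = lag(k-1) - lag(k)`), then `prod_i_j` for i, j over the nine
#' first-order columns in that order.
#'
#' @param rd length-T motion index (relative displacement), T > 5.
#' @return T x 90 matrix with named columns.
#' @export
volterra_expansion <- function(rd) {
  rd <- as.numeric(rd)
  t_len <- length(rd)
  if (t_len <= 5) stop("series too short for a lag-five expansion")
  lags <- vapply(0:4, function(k) c(rep(rd[1], k), rd)[seq_len(t_len)],
                 numeric(t_len))
  colnames(lags) <- paste0("lag", 0:4)
  diffs <- lags[, 1:4, drop = FALSE] - lags[, 2:5, drop = FALSE]
  colnames(diffs) <- paste0("diff", 1:4)
  first <- cbind(lags, diffs)
  prods <- matrix(0, t_len, 81)
  nm <- character(81)
  idx <- 0
  for (i in 1:9) {
    for (j in 1:9) {
      idx <- idx + 1
      prods[, idx] <- first[, i] * first[, j]
      nm[idx] <- paste0("prod_", colnames(first)[i], "_", colnames(first)[j])
    }
  }
  colnames(prods) <- nm
  cbind(first, prods)
}

#' Discrete cosine nuisance set implementing a band-pass filter
#'
#' Component k of the DCT basis over T volumes has frequency
#' `f_k = k / (2 * T * TR)`. The returned nuisance set contains the constant
#' (k = 0) plus every component with `f_k < f_low` or `f_k > f_high`;
#' including these as regressors and keeping residuals projects out all
#' fluctuations outside the pass band. Columns are unit-normalized and
#' mutually orthogonal.
#'
#' For 148 volumes at TR = 2 s and a 0.009-0.1 Hz band this yields 94
#' columns (1 constant + 5 low-frequency + 88 high-frequency).
#'
#' @param n_volumes T.
#' @param tr repetition time, seconds.
#' @param f_low,f_high pass-band edges in Hz; `0 <= f_low < f_high <=`
#'   Nyquist.
#' @return T x K orthonormal matrix; column names `dct0`, `dctk` record the
#'   component indices; attribute `frequencies` gives f_k per column.
#' @export
dct_bandpass_set <- function(n_volumes, tr, f_low = 0.009, f_high = 0.1) {
  stopifnot(n_volumes >= 2, tr > 0)
  nyquist <- 1 / (2 * tr)
  if (!(f_low >= 0 && f_low < f_high && f_high <= nyquist + 1e-12)) {
    stop("invalid band: need 0 <= f_low < f_high <= Nyquist")
  }
  t_idx <- seq_len(n_volumes)
  k_all <- seq_len(n_volumes - 1)
  f_k <- k_all / (2 * n_volumes * tr)
  keep <- k_all[f_k < f_low | f_k > f_high]
  basis <- matrix(1 / sqrt(n_volumes), n_volumes, 1 + length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    basis[, i + 1] <- sqrt(2 / n_volumes) *
      cos(pi * (2 * t_idx - 1) * k / (2 * n_volumes))
  }
  colnames(basis) <- paste0("dct", c(0L, keep))
  attr(basis, "frequencies") <- c(0, keep / (2 * n_volumes * tr))
  basis
}

#' Reduce stacked confound columns to leading SVD components
#'
#' Mean-centers and unit-variance scales each confound column (dropping
#' constant columns), stacks motion and artifact blocks, and keeps the
#' smallest number of left temporal singular vectors needed to explain at
#' least `variance_fraction` of the total variance. The retained components
#' are orthonormal.
#'
#' @param motion_block T x p motion confounds (e.g. [volterra_expansion()]).
#' @param artifact_block T x q artifact series (columns), or `NULL`.
#' @param variance_fraction fraction of variance to retain, in (0, 1].
#' @return T x m matrix of orthonormal components; attribute `m` records the
#'   count and `variance_explained` the achieved fraction.
#' @export
assemble_confounds <- function(motion_block, artifact_block = NULL,
                               variance_fraction = 0.99) {
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  stack <- cbind(motion_block, artifact_block)
  stack <- as.matrix(stack)
  stack <- sweep(stack, 2, colMeans(stack))
  sds <- sqrt(colMeans(stack^2))
  keep <- sds > 1e-12
  if (!any(keep)) stop("all confound columns are constant")
  stack <- sweep(stack[, keep, drop = FALSE], 2, sds[keep], "/")
  sv <- svd(stack)
  ev <- sv$d^2
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= variance_fraction - 1e-12)[1]
  comps <- sv$u[, seq_len(m), drop = FALSE]
  colnames(comps) <- paste0("svd_comp_", seq_len(m))
  attr(comps, "m") <- m
  attr(comps, "variance_explained") <- cum[m]
  comps
}

#' Assemble the full per-subject confound design
#'
#' Combines the relative-displacement Volterra expansion and artifact series
#' into SVD-reduced components, and appends the DCT band-pass nuisance set.
#'
#' @param rd length-T relative displacement series.
#' @param artifact_series 3 x T (or q x T) artifact signal matrix, or `NULL`.
#' @param tr repetition time (s).
#' @param f_low,f_high pass band (Hz).
#' @param variance_fraction SVD retention fraction.
#' @return list with `reduced` (T x m components), `dct` (T x K set),
#'   `design` (their column-bind), and counts `m`, `k_dct`.
#' @export
build_confound_design <- function(rd, artifact_series = NULL, tr = 2,
                                  f_low = 0.009, f_high = 0.1,
                                  variance_fraction = 0.99) {
  motion <- volterra_expansion(rd)
  art <- if (!is.null(artifact_series)) t(as.matrix(artifact_series)) else NULL
  reduced <- assemble_confounds(motion, art, variance_fraction)
  dct <- dct_bandpass_set(length(rd), tr, f_low, f_high)
  list(reduced = reduced, dct = dct, design = cbind(reduced, dct),
       m = attr(reduced, "m"), k_dct = ncol(dct))
}
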