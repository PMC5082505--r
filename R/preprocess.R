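# Subject-level preprocessing: ROI extraction, motion summaries, despiking.

#' Extract a standardized ROI time series from a voxel block
#'
#' Removes each voxel's temporal mean, takes the first temporal mode of a
#' singular-value decomposition across voxels (the dominant temporal
#' pattern, downweighting atypical voxels), flips its sign to match the
#' across-voxel mean series, and z-scores it to unit variance over volumes.
#'
#' @param voxel_matrix voxels x T numeric matrix (>= 1 voxel, T >= 3).
#' @return length-T numeric vector with unit sample variance; attribute
#'   `provenance` records `"svd_mode"`.
#' @export
extract_roi_series <- function(voxel_matrix) {
  voxel_matrix <- as.matrix(voxel_matrix)
  if (ncol(voxel_matrix) < 3) stop("need at least 3 volumes")
  if (any(!is.finite(voxel_matrix))) stop("non-finite voxel data")
  centered <- voxel_matrix - rowMeans(voxel_matrix)
  if (max(abs(centered)) < 1e-12) {
    stop("degenerate input: all voxels temporally constant")
  }
  sv <- svd(centered, nu = 0, nv = 1)
  mode <- sv$v[, 1]
  mean_series <- colMeans(centered)
  if (sum(mode * mean_series) < 0) mode <- -mode
  s <- stats::sd(mode)
  if (s < 1e-15) stop("degenerate input: first temporal mode is constant")
  out <- (mode - mean(mode)) / s
  attr(out, "provenance") <- "svd_mode"
  out
}

rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  mx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  my <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  mz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  mx %*% my %*% mz
}

rigid_transform <- function(p) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation_matrix(p[4], p[5], p[6])
  m[1:3, 4] <- p[1:3]
  m
}

#' Root-mean-square relative displacement between consecutive volumes
#'
#' Converts six rigid-body realignment parameters per volume into a single
#' scalar displacement series: for each pair of consecutive volumes the
#' relative transform \eqn{M = T_t T_{t-1}^{-1}} is decomposed into
#' \eqn{A = R(M) - I} and translation \eqn{t}, and
#' \eqn{rd_t = \sqrt{(r^2/5)\,\mathrm{tr}(A^\top A) + t^\top t}} with
#' sphere radius \eqn{r} (head modelled as a sphere, so rotations are
#' weighted by the displacement they induce at its surface). The first
#' element is 0 by convention.
#'
#' @param params T x 6 matrix: columns 1-3 translations (mm), 4-6 rotations
#'   (radians), i.e. translations-then-rotations; use [read_motion_file()]
#'   to normalize other file dialects first.
#' @param radius sphere radius in mm (default 80).
#' @return list with `rd` (length-T, mm, `rd[1] = 0`) and `mean_rd`.
#' @export
relative_displacement <- function(params, radius = 80) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, radius > 0)
  if (any(!is.finite(params))) stop("non-finite motion parameters")
  t_len <- nrow(params)
  rd <- numeric(t_len)
  m_prev <- rigid_transform(params[1, ])
  for (t in seq_len(t_len)[-1]) {
    m_cur <- rigid_transform(params[t, ])
    m <- m_cur %*% solve(m_prev)
    a <- m[1:3, 1:3] - diag(3)
    tv <- m[1:3, 4]
    rd[t] <- sqrt(radius^2 / 5 * sum(a * a) + sum(tv * tv))
    m_prev <- m_cur
  }
  list(rd = rd, mean_rd = mean(rd))
}

#' Flag high-motion subjects relative to the control interquartile range
#'
#' A subject is flagged when their mean relative displacement exceeds the
#' upper Tukey fence of the control distribution,
#' `Q3(controls) + 1.5 * IQR(controls)` (type-7 quantiles). Only the upper
#' fence is used: the concern is excessive movers, not unusually still ones.
#'
#' @param mean_rd_controls mean RD of the control subjects (>= 4 values).
#' @param mean_rd_all mean RD of every subject to be flagged.
#' @return logical vector parallel to `mean_rd_all`.
#' @export
flag_motion_outliers <- function(mean_rd_controls, mean_rd_all) {
  if (length(mean_rd_controls) < 4) stop("need at least 4 control values")
  q <- stats::quantile(mean_rd_controls, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  mean_rd_all > fence
}

#' Replace spikes in a series by linear interpolation
#'
#' Simple despiker: points whose robust z-score (median/MAD) exceeds the
#' threshold are replaced by linear interpolation between the flanking
#' non-spike points (nearest value at the ends). Intended as an optional
#' plumbing stage; off by default in the pipeline.
#'
#' @param series numeric vector, length >= 5.
#' @param z_threshold robust z-score cutoff (default 5).
#' @return despiked series of the same length.
#' @export
despike_interpolate <- function(series, z_threshold = 5) {
  stopifnot(length(series) >= 5)
  med <- stats::median(series)
  mad <- stats::mad(series)
  if (mad < 1e-15) return(series)
  spike <- abs(series - med) / mad > z_threshold
  if (!any(spike)) return(series)
  if (all(spike)) return(rep(med, length(series)))
  idx <- seq_along(series)
  series[spike] <- stats::approx(idx[!spike], series[!spike],
                                 xout = idx[spike], rule = 2)$y
  series
}
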