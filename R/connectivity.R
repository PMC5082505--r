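# Edge-level connectivity statistics and subject-level matrices.

# Drop nuisance columns that make [seed | nuisance] rank deficient.
prune_design <- function(seed_col, nuisance) {
  if (is.null(nuisance)) return(NULL)
  nuisance <- as.matrix(nuisance)
  x <- cbind(seed_col, nuisance)
  qr_x <- qr(x)
  if (qr_x$rank == ncol(x)) return(nuisance)
  keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
  keep <- setdiff(keep, 1L) - 1L
  warning("dropping ", ncol(nuisance) - length(keep),
          " rank-deficient nuisance column(s)")
  nuisance[, keep, drop = FALSE]
}

#' Connectivity statistic for one directed ROI pair
#'
#' Regresses the target series on the seed series plus nuisance regressors
#' (SVD-reduced confound components and the DCT band-pass set), with serial
#' correlation estimated by ReML over an exponential component family. The
#' seed coefficient's t statistic is referred to the t distribution at the
#' Satterthwaite effective degrees of freedom and converted to a signed
#' standard-normal deviate, so Z is calibrated despite the df lost to
#' confounds, filtering and autocorrelation.
#'
#' @param target,seed length-T series.
#' @param confounds nuisance matrix (T x m), a list with a `design` element
#'   as returned by [build_confound_design()], or `NULL` (intercept only).
#' @param family an [ar_family()]; built automatically if `NULL`.
#' @param ... passed to [reml_fit()].
#' @return list with `beta`, `t_stat`, `eff_df`, `z`, `m_confounds`,
#'   `converged`.
#' @export
edge_statistic <- function(target, seed, confounds = NULL, family = NULL,
                           ...) {
  target <- as.numeric(target)
  seed <- as.numeric(seed)
  t_len <- length(target)
  stopifnot(length(seed) == t_len)
  if (is.list(confounds) && !is.null(confounds$design)) {
    confounds <- confounds$design
  }
  if (is.null(confounds)) confounds <- matrix(1, t_len, 1)
  confounds <- prune_design(seed, confounds)
  if (is.null(family)) family <- ar_family(t_len)
  x <- cbind(seed = seed, confounds)
  fit <- reml_fit(target, x, family, ...)
  z <- t_to_z(fit$t_stat, fit$eff_df)
  list(beta = fit$beta[1], t_stat = fit$t_stat, eff_df = fit$eff_df,
       z = z, m_confounds = ncol(confounds), converged = fit$converged)
}

#' Symmetric Z connectivity matrix for one subject
#'
#' Computes the df-corrected Z statistic for every unique ROI pair. Two
#' estimators are available:
#'
#' * `method = "pooled"` (default): one ReML fit of the autocorrelation is
#'   pooled across all ROI series of the subject (standardized first), the
#'   shared whitening is applied to series and nuisance design, nuisance
#'   columns are projected out once, and every edge's t statistic is
#'   obtained from the partial correlations of the whitened residuals with
#'   residual df `T - m - 1`. The statistic is symmetric in seed and
#'   target, so the seed/target average is exact by construction. This is
#'   the estimator used at connectome scale.
#' * `method = "per_edge"`: a full ReML fit per directed pair, with
#'   `z[i, j]` the average of the two Z values obtained with each ROI as
#'   seed. Identical in expectation, much slower; practical for ROI-level
#'   (e.g. 8-ROI default-mode) analyses.
#'
#' @param roi_series ROI x T matrix, or a `subject_record`.
#' @param confounds nuisance design as in [edge_statistic()]; if `NULL` and
#'   a `subject_record` is supplied, the full confound design (Volterra RD
#'   expansion + artifact series, SVD-reduced, plus DCT set) is built.
#' @param method `"pooled"` or `"per_edge"`.
#' @param family an [ar_family()]; built automatically if `NULL`.
#' @param tr repetition time, used only when the confound design must be
#'   built from a `subject_record`.
#' @param ... passed to the underlying ReML fitters.
#' @return object of class `connectivity_matrix`: list with `z` (N x N
#'   symmetric, `NA` diagonal), `eff_df`, `roi_ids`, `method`.
#' @export
connectivity_matrix <- function(roi_series, confounds = NULL,
                                method = c("pooled", "per_edge"),
                                family = NULL, tr = 2, ...) {
  method <- match.arg(method)
  if (inherits(roi_series, "subject_record")) {
    subj <- roi_series
    roi_series <- subj$roi_series
    if (is.null(confounds)) {
      rd <- relative_displacement(subj$motion_params)$rd
      confounds <- build_confound_design(rd, subj$artifact_series, tr = tr)
    }
  }
  roi_series <- as.matrix(roi_series)
  n_roi <- nrow(roi_series)
  stopifnot(n_roi >= 2)
  t_len <- ncol(roi_series)
  if (is.list(confounds) && !is.null(confounds$design)) {
    confounds <- confounds$design
  }
  if (is.null(confounds)) confounds <- matrix(1, t_len, 1)
  confounds <- as.matrix(confounds)
  roi_ids <- rownames(roi_series) %||% paste0("roi", seq_len(n_roi))
  if (is.null(family)) family <- ar_family(t_len)

  if (method == "pooled") {
    y <- t(roi_series)
    pooled <- reml_pooled(y, confounds, family, ...)
    w <- pooled$whitener
    yw <- w %*% scale(y)
    xw <- w %*% confounds
    qr_x <- qr(xw)
    rank_x <- qr_x$rank
    res <- qr.resid(qr_x, yw)
    d <- colSums(res^2)
    if (any(d < 1e-12)) stop("ROI series degenerate after confound removal")
    r <- crossprod(res) / sqrt(tcrossprod(d))
    r[r > 0.999999] <- 0.999999
    r[r < -0.999999] <- -0.999999
    eff_df <- t_len - rank_x - 1
    t_mat <- r * sqrt(eff_df / (1 - r^2))
    z <- t_to_z(t_mat, eff_df)
    diag(z) <- NA_real_
  } else {
    p_fam <- family
    z <- matrix(NA_real_, n_roi, n_roi)
    eff_df_sum <- 0; n_edges <- 0
    for (i in seq_len(n_roi - 1)) {
      for (j in (i + 1):n_roi) {
        e1 <- edge_statistic(roi_series[i, ], roi_series[j, ], confounds,
                             p_fam, ...)
        e2 <- edge_statistic(roi_series[j, ], roi_series[i, ], confounds,
                             p_fam, ...)
        z[i, j] <- z[j, i] <- (e1$z + e2$z) / 2
        eff_df_sum <- eff_df_sum + (e1$eff_df + e2$eff_df) / 2
        n_edges <- n_edges + 1
      }
    }
    eff_df <- eff_df_sum / n_edges
  }
  dimnames(z) <- list(roi_ids, roi_ids)
  structure(list(z = z, eff_df = eff_df, roi_ids = roi_ids, method = method,
                 m_confounds = ncol(confounds)),
            class = "connectivity_matrix")
}

#' Regress a motion index out of one edge across subjects
#'
#' Across all participants (controls and patients combined), each
#' connection is regressed on the subjects' mean relative displacement and
#' replaced by the residual plus the grand mean, removing any group-level
#' association between connectivity and head motion.
#'
#' @param edge_values per-subject values of one edge (length >= 3).
#' @param mean_rd per-subject mean relative displacement.
#' @return residualized values on the original scale.
#' @export
residualize_motion <- function(edge_values, mean_rd) {
  stopifnot(length(edge_values) == length(mean_rd),
            length(edge_values) >= 3)
  if (stats::sd(mean_rd) < 1e-12) {
    warning("mean RD is constant across subjects; returning input unchanged")
    return(edge_values)
  }
  fit <- stats::lm.fit(cbind(1, mean_rd), edge_values)
  fit$residuals + mean(edge_values)
}

#' Residualize every edge of a stack of connectivity matrices
#'
#' Applies [residualize_motion()] to each upper-triangle edge of a list of
#' subject connectivity matrices in one vectorized pass.
#'
#' @param conn_list list of `connectivity_matrix` objects (same ROIs).
#' @param mean_rd per-subject mean RD, parallel to `conn_list`.
#' @return list of `connectivity_matrix` objects with residualized `z`.
#' @export
residualize_cohort <- function(conn_list, mean_rd) {
  stopifnot(length(conn_list) == length(mean_rd), length(conn_list) >= 3)
  if (stats::sd(mean_rd) < 1e-12) {
    warning("mean RD is constant across subjects; returning input unchanged")
    return(conn_list)
  }
  z_stack <- vapply(conn_list, function(cm) cm$z[upper.tri(cm$z)],
                    numeric(sum(upper.tri(conn_list[[1]]$z))))
  z_stack <- t(as.matrix(z_stack))  # subjects x edges
  x <- cbind(1, mean_rd)
  beta <- solve(crossprod(x), crossprod(x, z_stack))
  res <- z_stack - x %*% beta
  res <- sweep(res, 2, colMeans(z_stack), "+")
  lapply(seq_along(conn_list), function(s) {
    cm <- conn_list[[s]]
    z <- cm$z
    z[upper.tri(z)] <- res[s, ]
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
    cm$z <- z
    cm
  })
}
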