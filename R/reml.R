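# Covariance-component model of serial correlation in the connectivity GLM,
# estimated by restricted maximum likelihood (ReML).

#' Exponential autocorrelation component family
#'
#' Serial correlation in resting-state GLM errors is modelled as a
#' non-negative mixture of exponentials,
#' \eqn{Q_i(t, t') = \exp(-\ln 2 \, |t - t'| / h_i)}, with half-lives
#' spanning 0.5 to 64 TRs — a flexible family, since an AR(1)-plus-white
#' model is known to be insufficient for resting-state data. An identity
#' (white-noise) component is appended by default: without it the mixture
#' cannot represent near-white errors and ReML becomes ill-conditioned.
#'
#' @param n_volumes T; number of time points (>= 8).
#' @param half_lives exponential half-lives in TR units.
#' @param include_identity append an identity component (default `TRUE`).
#' @return object of class `ar_family`: list with `components` (list of
#'   T x T matrices), `half_lives`, `include_identity`.
#' @export
ar_family <- function(n_volumes,
                      half_lives = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                      include_identity = TRUE) {
  stopifnot(n_volumes >= 8, all(half_lives > 0))
  lag <- abs(outer(seq_len(n_volumes), seq_len(n_volumes), "-"))
  comps <- lapply(half_lives, function(h) exp(-log(2) * lag / h))
  names(comps) <- paste0("h", half_lives)
  if (include_identity) comps$identity <- diag(n_volumes)
  structure(list(components = comps, half_lives = half_lives,
                 include_identity = include_identity),
            class = "ar_family")
}

# V = sum(lambda_i Q_i), projected to positive definite (eigenvalue floor
# relative to mean diagonal). Returns V, its inverse and log-determinant.
build_covariance <- function(lambda, components) {
  t_len <- nrow(components[[1]])
  v <- matrix(0, t_len, t_len)
  for (i in seq_along(components)) v <- v + lambda[i] * components[[i]]
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(mean(diag(v))) * 1e-7) {
    eig <- eigen(v, symmetric = TRUE)
    floor_val <- max(mean(abs(diag(v))), 1e-12) * 1e-6
    vals <- pmax(eig$values, floor_val)
    v <- eig$vectors %*% (vals * t(eig$vectors))
    return(list(v = v, iv = eig$vectors %*% ((1 / vals) * t(eig$vectors)),
                logdet = sum(log(vals))))
  }
  list(v = v, iv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

# Core ReML iteration shared by the single-series and pooled estimators.
# `s_mat` is the second-moment matrix of the data: y %*% t(y) for a single
# series, or tcrossprod(Y) / n for n pooled series. Fisher scoring on the
# restricted log-likelihood with Levenberg damping and step halving.
reml_engine <- function(s_mat, x, family, tol = 1e-6, max_iter = 64,
                        min_improve = 1e-3) {
  comps <- family$components
  q <- length(comps)
  t_len <- nrow(s_mat)
  p <- ncol(x)
  if (qr(x)$rank < p) stop("design matrix is rank deficient")
  # Initialize from the OLS residual variance, split across components.
  rx <- diag(t_len) - x %*% solve(crossprod(x), t(x))
  s0 <- sum(diag(rx %*% s_mat)) / (t_len - p)
  s0 <- max(s0, 1e-10)
  lambda <- rep(s0 / q, q)
  if (family$include_identity) {
    lambda[] <- 0.1 * s0 / max(1, q - 1)
    lambda[q] <- 0.9 * s0
  }

  objective <- function(vv) {
    xtivx <- crossprod(x, vv$iv %*% x)
    ld2 <- determinant(xtivx, logarithm = TRUE)$modulus
    ivx <- vv$iv %*% x
    p_mat <- vv$iv - ivx %*% solve(xtivx, t(ivx))
    obj <- -0.5 * (vv$logdet + as.numeric(ld2) + sum(p_mat * s_mat))
    list(obj = obj, p_mat = p_mat)
  }

  # Hyperparameters are optimized on the log scale (lambda = exp(gamma)),
  # so V is always a positive mixture of positive-definite components and
  # remains valid at every iterate; this also equalizes the scales of the
  # short- and long-half-life components in the scoring step.
  gamma <- log(lambda)
  vv <- build_covariance(exp(gamma), comps)
  cur <- objective(vv)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    obj_prev <- cur$obj
    lambda <- exp(gamma)
    p_mat <- cur$p_mat
    pq <- lapply(comps, function(qi) p_mat %*% qi)
    ps <- p_mat %*% s_mat
    g <- vapply(seq_len(q), function(i) {
      -0.5 * sum(diag(pq[[i]])) + 0.5 * sum(pq[[i]] * t(ps))
    }, numeric(1))
    h <- matrix(0, q, q)
    for (i in seq_len(q)) {
      for (j in i:q) {
        h[i, j] <- h[j, i] <- 0.5 * sum(pq[[i]] * t(pq[[j]]))
      }
    }
    g_g <- g * lambda
    h_g <- h * tcrossprod(lambda)
    ridge <- max(diag(h_g)) * 1e-6 + 1e-12
    step <- tryCatch(solve(h_g + ridge * diag(q), g_g),
                     error = function(e) g_g / (diag(h_g) + ridge))
    step <- pmin(pmax(step, -8), 8)
    # Step halving against the restricted likelihood keeps scoring stable
    # when the exponential components are nearly collinear.
    improved <- FALSE
    for (half in 0:5) {
      cand <- gamma + step / 2^half
      vv_c <- build_covariance(exp(cand), comps)
      cur_c <- objective(vv_c)
      if (is.finite(cur_c$obj) && cur_c$obj >= cur$obj - 1e-10) {
        gamma_new <- cand; vv <- vv_c; cur <- cur_c
        improved <- TRUE
        break
      }
    }
    if (!improved) { converged <- TRUE; break }
    rel <- sum(abs(exp(gamma_new) - lambda)) / (sum(abs(lambda)) + 1e-12)
    gain <- cur$obj - obj_prev
    gamma <- gamma_new
    # Stop on a negligible hyperparameter update, or once the restricted
    # likelihood has entered its flat tail: further refinement of lambda
    # no longer changes V at a level that matters for inference.
    if (rel < tol || (iter > 1 && gain < min_improve)) {
      converged <- TRUE
      break
    }
  }
  lambda <- exp(gamma)
  if (!converged) {
    warning("ReML did not converge within ", max_iter, " iterations")
  }
  names(lambda) <- names(comps)
  list(lambda = lambda, v = vv$v, iv = vv$iv, converged = converged,
       iterations = iter)
}

# Inverse symmetric square root via eigendecomposition.
inv_sqrt_matrix <- function(v) {
  eig <- eigen(v, symmetric = TRUE)
  vals <- pmax(eig$values, max(eig$values) * 1e-10)
  eig$vectors %*% ((1 / sqrt(vals)) * t(eig$vectors))
}

# Satterthwaite effective degrees of freedom for a residual-forming matrix
# R and error covariance V (both in the same, typically whitened, space):
# nu = tr(RV)^2 / tr(RVRV).
satterthwaite_df <- function(r_mat, v_mat) {
  rv <- r_mat %*% v_mat
  sum(diag(rv))^2 / sum(rv * t(rv))
}

#' Fit a GLM with ReML-estimated error autocorrelation
#'
#' Estimates regression coefficients and autocorrelation hyperparameters
#' simultaneously: the error covariance is \eqn{V = \sum_i \lambda_i Q_i}
#' over an [ar_family()], hyperparameters are estimated by Fisher-scoring
#' ReML on the residual-forming projection of the data, and coefficients by
#' generalized least squares under the fitted V. Hyperparameters are
#' optimized on the log scale, so the fitted V is a non-negative mixture of
#' positive-definite components and always a valid covariance.
#'
#' The effective degrees of freedom for a contrast use the Satterthwaite
#' form \eqn{\nu = \mathrm{tr}(RV)^2 / \mathrm{tr}(RVRV)} with R the
#' residual-forming matrix of the whitened design, which accounts for the
#' df lost to confound removal, filtering and residual autocorrelation.
#'
#' @param y length-T response.
#' @param x T x p design matrix, full column rank, T > p.
#' @param family an [ar_family()]; must match T.
#' @param contrast contrast vector (default: first column's coefficient).
#' @param tol relative hyperparameter tolerance for convergence.
#' @param max_iter maximum ReML iterations.
#' @param min_improve restricted-likelihood improvement below which the
#'   fit is declared converged (the likelihood's flat tail).
#' @return list with `beta`, `lambda` (clipped at 0), `v` (fitted T x T
#'   covariance), `eff_df`, `t_stat` (for `contrast`), `se`, `converged`.
#' @export
reml_fit <- function(y, x, family, contrast = NULL, tol = 1e-6,
                     max_iter = 64, min_improve = 1e-3) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  t_len <- length(y)
  stopifnot(nrow(x) == t_len, t_len > ncol(x))
  stopifnot(inherits(family, "ar_family"),
            nrow(family$components[[1]]) == t_len)
  if (is.null(contrast)) contrast <- c(1, rep(0, ncol(x) - 1))
  fit <- reml_engine(tcrossprod(y), x, family, tol = tol,
                     max_iter = max_iter, min_improve = min_improve)
  xtivx <- crossprod(x, fit$iv %*% x)
  beta <- solve(xtivx, crossprod(x, fit$iv %*% y))
  cov_beta <- solve(xtivx)
  se <- sqrt(drop(t(contrast) %*% cov_beta %*% contrast))
  w <- inv_sqrt_matrix(fit$v)
  xw <- w %*% x
  rw <- diag(t_len) - xw %*% solve(crossprod(xw), t(xw))
  vw <- w %*% fit$v %*% w
  eff_df <- satterthwaite_df(rw, vw)
  list(beta = drop(beta), lambda = fit$lambda, v = fit$v,
       eff_df = eff_df, t_stat = drop(t(contrast) %*% beta) / se, se = se,
       converged = fit$converged, iterations = fit$iterations)
}

#' Pooled ReML estimate of error covariance across many series
#'
#' Estimates one autocorrelation structure shared by all columns of `y_mat`
#' (each standardized to unit variance before pooling), analogous to
#' pooling ReML over voxels in imaging GLMs. Used by the fast pooled
#' connectivity estimator; only the correlation structure of the result
#' matters downstream, since per-edge residual variances are re-estimated.
#'
#' @param y_mat T x N matrix of series.
#' @param x T x p design (nuisance) matrix.
#' @param family an [ar_family()].
#' @inheritParams reml_fit
#' @return list with `lambda`, `v`, `whitener` (V^{-1/2}), `converged`.
#' @export
reml_pooled <- function(y_mat, x, family, tol = 1e-4, max_iter = 32,
                        min_improve = 1e-3) {
  y_mat <- as.matrix(y_mat)
  y_mat <- sweep(y_mat, 2, colMeans(y_mat))
  sds <- sqrt(colMeans(y_mat^2))
  y_mat <- sweep(y_mat, 2, pmax(sds, 1e-12), "/")
  s_mat <- tcrossprod(y_mat) / ncol(y_mat)
  fit <- reml_engine(s_mat, as.matrix(x), family, tol = tol,
                     max_iter = max_iter, min_improve = min_improve)
  list(lambda = fit$lambda, v = fit$v,
       whitener = inv_sqrt_matrix(fit$v), converged = fit$converged,
       iterations = fit$iterations)
}
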