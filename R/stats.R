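# Group and single-case statistics.

test_result <- function(statistic, df, p, direction = sign(statistic),
                        family_size = 1L) {
  list(statistic = statistic, df = df, p_two_tailed = p,
       direction = direction, family_size = family_size,
       p_adjusted = bonferroni_adjust(p, family_size))
}

#' Single-case t-test of a patient against a control sample
#'
#' Crawford-Howell style pooled-variance comparison of one observation to a
#' control sample: \eqn{t = (x_p - \bar{x}_c) / (s_c \sqrt{1 + 1/n_c})}
#' with \eqn{n_c - 1} degrees of freedom. The \eqn{1 + 1/n_c} inflation
#' treats the patient as a sample of one rather than a fixed population
#' value, keeping the test calibrated at small control n.
#'
#' @param patient_value scalar patient score.
#' @param control_values control sample (>= 2 values, nonzero variance).
#' @param one_tailed if `TRUE`, halve the p-value in the observed direction
#'   (used for directional lesion predictions).
#' @return a test-result list: `statistic`, `df`, `p_two_tailed` (or
#'   one-tailed when requested, see `direction`), `direction`.
#' @export
single_case_t <- function(patient_value, control_values, one_tailed = FALSE) {
  n_c <- length(control_values)
  stopifnot(n_c >= 2)
  s_c <- stats::sd(control_values)
  if (s_c < 1e-15) stop("control variance is zero")
  t_stat <- (patient_value - mean(control_values)) / (s_c * sqrt(1 + 1 / n_c))
  df <- n_c - 1
  p <- 2 * stats::pt(-abs(t_stat), df)
  if (one_tailed) p <- p / 2
  test_result(t_stat, df, p)
}

#' Two-sample t-test on a group coefficient with a nuisance covariate
#'
#' Fits `value ~ intercept + group + covariate` by least squares and tests
#' the group coefficient (df = n - 3). With `covariate = NULL`, or when the
#' covariate is collinear with the design (then dropped with a warning),
#' this reduces to the unpaired pooled-variance t-test (df = n - 2).
#'
#' @param values numeric outcomes.
#' @param group factor/character with two levels, or 0/1; the test is on
#'   the second level minus the first.
#' @param covariate optional nuisance covariate (e.g. sex).
#' @return test-result list with `statistic`, `df`, `p_two_tailed`.
#' @export
pooled_t_covariate <- function(values, group, covariate = NULL) {
  g <- if (is.numeric(group)) group else as.numeric(factor(group)) - 1
  stopifnot(length(unique(g)) == 2, min(table(g)) >= 2)
  x <- cbind(intercept = 1, group = g)
  if (!is.null(covariate)) {
    cv <- if (is.numeric(covariate)) covariate
          else as.numeric(factor(covariate)) - 1
    x_full <- cbind(x, covariate = cv)
    if (qr(x_full)$rank < ncol(x_full)) {
      warning("covariate collinear with design; dropped")
    } else {
      x <- x_full
    }
  }
  n <- length(values)
  stopifnot(n > ncol(x))
  fit <- stats::lm.fit(x, values)
  rss <- sum(fit$residuals^2)
  df <- n - ncol(x)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  t_stat <- fit$coefficients["group"] / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  test_result(unname(t_stat), df, unname(p))
}

#' Combine independent z-scores by Stouffer's method
#'
#' \eqn{Z = \sum_i z_i / \sqrt{k}}; the two-tailed p is
#' \eqn{2(1 - \Phi(|Z|))}, computed on the log scale so extreme combined
#' statistics do not underflow.
#'
#' @param z_values finite z-scores (k >= 1).
#' @return test-result list with the combined `statistic` and `p_two_tailed`.
#' @export
stouffer_combine <- function(z_values) {
  z_values <- z_values[is.finite(z_values)]
  if (length(z_values) == 0) stop("no finite z-values to combine")
  z <- sum(z_values) / sqrt(length(z_values))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  test_result(z, df = Inf, p = p)
}

#' Convert a normative percentile to a z-score
#'
#' @param percentile value in (0, 100).
#' @return \eqn{z = \Phi^{-1}(\mathrm{percentile}/100)}.
#' @export
percentile_to_z <- function(percentile) {
  stopifnot(all(percentile > 0 & percentile < 100))
  stats::qnorm(percentile / 100)
}

#' Bonferroni adjustment
#'
#' @param p p-value(s).
#' @param m family size (>= 1).
#' @return `min(1, m * p)`, vectorized.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 10 and there
#' are no ties; otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return test-result list with the rank-sum `statistic` (Mann-Whitney W
#'   for sample `a`) and `p_two_tailed`.
#' @export
ranksum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- (length(a) + length(b)) <= 10 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  test_result(unname(wt$statistic), df = NA_real_, p = wt$p.value,
              direction = sign(stats::median(a) - stats::median(b)))
}
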