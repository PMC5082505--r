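test_that("single-case t matches the pooled-variance closed form", {
  res <- single_case_t(2, c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(4 / 3), tolerance = 1e-10)
  expect_identical(res$df, 2)
  expect_equal(res$p_two_tailed, 0.1217, tolerance = 1e-3)

  null_res <- single_case_t(5, c(4, 5, 6))
  expect_equal(null_res$statistic, 0)
  expect_equal(null_res$p_two_tailed, 1)

  # as n grows with unit sd, t -> (x_p - mean)
  set.seed(40)
  big <- rnorm(20000)
  big <- (big - mean(big)) / sd(big) + 10
  expect_equal(single_case_t(11.5, big)$statistic, 1.5, tolerance = 0.01)

  expect_error(single_case_t(1, c(2, 2, 2)), "zero")
})

test_that("single-case t is calibrated under the null", {
  set.seed(41)
  p_vals <- replicate(4000, {
    controls <- rnorm(40)
    single_case_t(rnorm(1), controls)$p_two_tailed
  })
  expect_lt(abs(mean(p_vals < 0.05) - 0.05), 0.015)
})

test_that("group t with covariate matches a normal-equations oracle", {
  set.seed(42)
  n <- 24
  group <- rep(0:1, each = n / 2)
  covar <- rnorm(n)
  y <- 0.5 * group + 0.3 * covar + rnorm(n)
  res <- pooled_t_covariate(y, group, covar)
  # independent least-squares solve
  x <- cbind(1, group, covar)
  beta <- solve(t(x) %*% x) %*% t(x) %*% y
  resid <- y - x %*% beta
  s2 <- sum(resid^2) / (n - 3)
  se <- sqrt(s2 * solve(t(x) %*% x)[2, 2])
  expect_equal(res$statistic, drop(beta[2] / se), tolerance = 1e-10)
  expect_equal(res$df, n - 3)

  # orthogonal covariate: same group coefficient as the plain pooled t;
  # the t statistic agrees up to the one-df change in the error estimate
  covar_orth <- covar - mean(covar[group == 0]) * (1 - group) -
    mean(covar[group == 1]) * group
  plain <- t.test(y[group == 1], y[group == 0], var.equal = TRUE)
  res2 <- pooled_t_covariate(y, group, covar_orth)
  expect_equal(res2$statistic, unname(plain$statistic), tolerance = 0.05)
  no_cov <- pooled_t_covariate(y, group)
  expect_equal(no_cov$statistic, unname(plain$statistic),
               tolerance = 1e-8)
  expect_equal(no_cov$df, n - 2)

  same <- rep(c(3, 4, 5, 6), 2)
  expect_equal(pooled_t_covariate(same, rep(0:1, each = 4))$statistic, 0)

  expect_warning(pooled_t_covariate(y, group, group), "collinear")
})

test_that("affine transforms leave the group t unchanged", {
  set.seed(43)
  y <- rnorm(20)
  g <- rep(0:1, 10)
  a <- pooled_t_covariate(y, g)
  b <- pooled_t_covariate(100 + 7 * y, g)
  expect_equal(b$statistic, a$statistic, tolerance = 1e-10)
})

test_that("Stouffer combination follows sum over root k", {
  expect_equal(stouffer_combine(c(1, 1, 1, 1))$statistic, 2)
  z0 <- stouffer_combine(c(0, 0, 0))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p_two_tailed, 1)
  # six equal domain scores of -2.719: the combined statistic is -6.66
  expect_equal(stouffer_combine(rep(-2.719, 6))$statistic, -6.66,
               tolerance = 0.005)
  expect_equal(stouffer_combine(1.7)$statistic, 1.7)
  expect_error(stouffer_combine(numeric(0)), "no finite")
})

test_that("percentile-to-z conversion inverts the normal CDF", {
  expect_equal(percentile_to_z(50), 0)
  expect_equal(percentile_to_z(2.275), -2, tolerance = 1e-3)
  expect_equal(percentile_to_z(84.13), 1, tolerance = 1e-3)
  expect_error(percentile_to_z(0), "percentile")
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni_adjust(0.001, 28), 0.028)
  expect_equal(bonferroni_adjust(0.2, 16), 1)
  expect_equal(bonferroni_adjust(0.0004, 120), 0.048)
})

test_that("rank-sum test is exact for small samples and stable for ties", {
  res <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_two_tailed, 0.1, tolerance = 1e-10)
  same <- ranksum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_two_tailed, 0.9)

  # exact and approximate p agree at moderate n
  set.seed(44)
  diffs <- replicate(50, {
    a <- rnorm(10); b <- rnorm(10)
    exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    approx <- stats::wilcox.test(a, b, exact = FALSE,
                                 correct = TRUE)$p.value
    abs(approx - exact)
  })
  expect_lt(median(diffs), 0.02)
})
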