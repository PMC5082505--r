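test_that("autocorrelation components encode their half-lives", {
  fam <- ar_family(100)
  expect_length(fam$components, 9)  # 8 exponentials + identity
  h1 <- fam$components[["h1"]]
  expect_equal(h1[1, 2], 0.5)
  expect_true(all(vapply(fam$components, function(q) all(diag(q) == 1),
                         logical(1))))
  h64 <- fam$components[["h64"]]
  expect_equal(h64[1, 65], 0.5)
  expect_equal(h64[1, 100], 0.5^(99 / 64))
})

test_that("ReML recovers exact coefficients in the noiseless limit", {
  set.seed(10)
  x <- cbind(rnorm(60), 1)
  y <- drop(x %*% c(2, -1))
  fit <- reml_fit(y + rnorm(60, sd = 1e-9), x, ar_family(60))
  expect_equal(fit$beta, c(2, -1), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("white-noise fits give near-nominal effective df", {
  set.seed(11)
  fam <- ar_family(148)
  dfs <- replicate(60, {
    suppressWarnings(reml_fit(rnorm(148), matrix(1, 148, 1), fam))$eff_df
  })
  expect_lt(abs(median(dfs) - 147) / 147, 0.05)
})

test_that("rank-deficient designs error and degenerate nuisance is dropped", {
  set.seed(13)
  x <- cbind(rnorm(50), rnorm(50))
  x <- cbind(x, x[, 1])
  expect_error(reml_fit(rnorm(50), x, ar_family(50)), "rank deficient")
  seedv <- rnorm(50)
  expect_warning(
    edge_statistic(rnorm(50), seedv, confounds = cbind(1, seedv)),
    "rank-deficient")
})

test_that("edge Z is near-saturated for a near-identical pair", {
  set.seed(14)
  s <- rnorm(148)
  e <- edge_statistic(s + rnorm(148, sd = 0.01), s)
  expect_gt(e$z, 10)
})

test_that("edge Z matches the Fisher large-sample oracle at r = 0.5", {
  set.seed(15)
  zs <- replicate(200, {
    x <- rnorm(148)
    y <- 0.5 * x + sqrt(0.75) * rnorm(148)
    suppressWarnings(edge_statistic(y, x))$z
  })
  oracle <- atanh(0.5) * sqrt(145)
  expect_lt(abs(mean(zs) - oracle), 0.5)
})

test_that("edge Z is invariant to rescaling and redundant confounds", {
  set.seed(16)
  x <- rnorm(120)
  y <- 0.4 * x + rnorm(120)
  conf <- cbind(1, sim_ar1(120, 0.3))
  base <- edge_statistic(y, x, conf)
  scaled <- edge_statistic(3.7 * y, 0.2 * x, conf)
  expect_equal(scaled$z, base$z, tolerance = 1e-5)
  # a nuisance column already in the design span changes nothing
  redundant <- suppressWarnings(
    edge_statistic(y, x, cbind(conf, conf %*% c(0.3, -1))))
  expect_equal(redundant$z, base$z, tolerance = 1e-5)
})

test_that("effective df shrinks as nuisance columns are added", {
  set.seed(17)
  y <- rnorm(148)
  x <- rnorm(148)
  fam <- ar_family(148)
  dct <- dct_bandpass_set(148, 2)
  nested <- list(matrix(1, 148, 1), dct[, 1:20], dct[, 1:60], dct)
  dfs <- vapply(nested, function(cf) {
    suppressWarnings(edge_statistic(y, x, cf, fam))$eff_df
  }, numeric(1))
  expect_true(all(diff(dfs) < 0))
})

test_that("connectivity matrices are symmetric, finite and equivariant", {
  spec <- tiny_spec()
  subj <- generate_subject(spec, "control", "M", seed = 31)
  cm <- connectivity_matrix(subj, method = "pooled")
  expect_true(isSymmetric(cm$z))
  off <- cm$z[upper.tri(cm$z)]
  expect_true(all(is.finite(off)))
  expect_true(all(is.na(diag(cm$z))))

  # ROI relabeling permutes rows/columns consistently
  perm <- sample(nrow(subj$roi_series))
  rd <- relative_displacement(subj$motion_params)$rd
  conf <- build_confound_design(rd, subj$artifact_series, tr = 2)
  cm1 <- connectivity_matrix(subj$roi_series, conf)
  cm2 <- connectivity_matrix(subj$roi_series[perm, ], conf)
  expect_equal(cm2$z, cm1$z[perm, perm], tolerance = 1e-8)
})

test_that("per-edge and pooled estimators agree on an 8-ROI subject", {
  spec <- cohort_spec(n_rois = 8, partition_sizes = rep(2L, 4L),
                      n_volumes = 148,
                      network_roles = c(DMN = 1L, FEN = 2L, thalamic = 3L,
                                        precuneus = 4L),
                      lesion_rois = 1L)
  subj <- generate_subject(spec, "control", "M", seed = 32)
  rd <- relative_displacement(subj$motion_params)$rd
  conf <- build_confound_design(rd, subj$artifact_series, tr = 2)
  pooled <- connectivity_matrix(subj$roi_series, conf, method = "pooled")
  edge <- suppressWarnings(
    connectivity_matrix(subj$roi_series, conf, method = "per_edge"))
  expect_identical(sum(!is.na(edge$z[upper.tri(edge$z)])), 28L)
  a <- pooled$z[upper.tri(pooled$z)]
  b <- edge$z[upper.tri(edge$z)]
  expect_gt(cor(a, b), 0.95)
  expect_lt(mean(abs(a - b)), 0.5)
})

test_that("motion residualization removes the RD association exactly", {
  set.seed(18)
  rd <- runif(30, 0.05, 0.3)
  edge <- 2 * rd
  expect_lt(var(residualize_motion(edge, rd) - mean(edge)), 1e-20)

  e2 <- rnorm(30)
  res <- residualize_motion(e2, rd)
  expect_lt(abs(cor(res, rd)), 1e-10)
  expect_equal(mean(res), mean(e2))

  expect_warning(residualize_motion(e2, rep(0.1, 30)), "constant")

  # vectorized cohort version agrees with the per-edge version
  conns <- lapply(1:6, function(i) {
    z <- random_symmetric(5)
    diag(z) <- NA
    structure(list(z = z, eff_df = 40, roi_ids = paste0("r", 1:5),
                   method = "pooled"), class = "connectivity_matrix")
  })
  mrd <- runif(6)
  out <- residualize_cohort(conns, mrd)
  e12 <- vapply(conns, function(cm) cm$z[1, 2], numeric(1))
  expect_equal(vapply(out, function(cm) cm$z[1, 2], numeric(1)),
               residualize_motion(e12, mrd), tolerance = 1e-12)
})
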