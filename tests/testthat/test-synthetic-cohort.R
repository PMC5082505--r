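test_that("partition construction assigns every ROI to exactly one network", {
  spec <- cohort_spec(n_rois = 6, partition_sizes = c(3, 3), n_volumes = 80,
                      alpha_lesion = 0, delta_within = 0, delta_tp = 0,
                      delta_df = 0, network_roles = c(DMN = 1L, FEN = 2L,
                                                      thalamic = 1L,
                                                      precuneus = 2L),
                      lesion_rois = 1L)
  part <- generate_partition(spec)
  expect_identical(part$labels, c(1L, 1L, 1L, 2L, 2L, 2L))

  expect_error(cohort_spec(n_rois = 6, partition_sizes = c(3, 4)),
               "sum to n_rois")

  set.seed(1)
  sizes <- as.vector(stats::rmultinom(1, 120 - 16, rep(1 / 16, 16))) + 1L
  spec16 <- cohort_spec(n_rois = 120, partition_sizes = sizes,
                        n_volumes = 80)
  part16 <- generate_partition(spec16)
  expect_length(part16$labels, 120)
  expect_length(unique(part16$labels), 16)
})

test_that("degenerate noise-free subject equals its network latents", {
  spec <- tiny_spec(noise_sd = 0, global_coupling = 0, within_coupling = 1,
                    base_rho = 0)
  subj <- generate_subject(spec, "control", "M", seed = 7)
  part <- generate_partition(spec)
  # all ROIs of one network carry identical series
  for (k in unique(part$labels)) {
    rows <- subj$roi_series[part$labels == k, ]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
})

test_that("subject generation is bit-identical under a repeated seed", {
  spec <- tiny_spec()
  a <- generate_subject(spec, "patient", "F", seed = 11)
  b <- generate_subject(spec, "patient", "F", seed = 11)
  expect_identical(a, b)
  c <- generate_subject(spec, "patient", "F", seed = 12)
  expect_false(identical(a$roi_series, c$roi_series))
})

test_that("within/between correlation gap matches the closed form", {
  spec <- cohort_spec(n_volumes = 2000, global_coupling = 0, base_rho = 0)
  subj <- generate_subject(spec, "control", "M", seed = 42)
  part <- generate_partition(spec)
  cc <- cor(t(subj$roi_series))
  same <- outer(part$labels, part$labels, "==") & upper.tri(cc)
  diff <- (!outer(part$labels, part$labels, "==")) & upper.tri(cc)
  gap <- mean(cc[same]) - mean(cc[diff])
  expect_lt(abs(gap - analytic_correlation_gap(spec)), 0.05)
})

test_that("latent AR(1) coefficient is calibrated", {
  spec <- cohort_spec(n_rois = 8, partition_sizes = rep(2L, 4L),
                      n_volumes = 5000, noise_sd = 0, global_coupling = 0,
                      within_coupling = 1, latent_ar = 0.3,
                      network_roles = c(DMN = 1L, FEN = 2L, thalamic = 3L,
                                        precuneus = 4L))
  subj <- generate_subject(spec, "control", "M", seed = 3)
  x <- subj$roi_series[1, ]
  ar1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(ar1 - 0.3), 0.05)
})

test_that("cohorts respect requested sizes, labels and determinism", {
  spec <- tiny_spec()
  coh <- generate_cohort(spec, 2, 1, seed = 5)
  expect_length(coh, 3)
  expect_identical(vapply(coh, `[[`, character(1), "group"),
                   c("control", "control", "patient"))
  coh2 <- generate_cohort(spec, 2, 1, seed = 5)
  expect_identical(coh, coh2)
})

test_that("lesion attenuation reduces patient lesion-ROI variance", {
  spec <- tiny_spec(alpha_lesion = 0.5)
  n <- 25
  vars <- vapply(seq_len(2 * n), function(i) {
    grp <- if (i <= n) "control" else "patient"
    subj <- generate_subject(spec, grp, "M", seed = 300 + i)
    mean(apply(subj$roi_series[spec$lesion_rois, , drop = FALSE], 1, var))
  }, numeric(1))
  expect_lt(mean(vars[(n + 1):(2 * n)]), mean(vars[1:n]))
})

test_that("voxel blocks reproduce the reference series and sign pattern", {
  s <- sin(seq_len(100) / 5)
  blk <- generate_voxel_block(s, 5, voxel_noise_sd = 0)
  expect_true(all(apply(blk, 1, function(r) max(abs(r - s))) < 1e-12))
  flipped <- generate_voxel_block(s, 5, voxel_noise_sd = 0,
                                  sign_flips = TRUE)
  expect_equal(flipped, -blk)
  set.seed(1)
  s2 <- rnorm(500)
  noisy <- generate_voxel_block(s2, 100, voxel_noise_sd = 1, seed = 9)
  expect_gt(cor(colMeans(noisy), s2), 0.9)
})

test_that("planted cross-network deltas shape the latent correlation", {
  spec <- cohort_spec()
  cc_c <- lesionconn:::latent_correlation(spec, "control")
  cc_p <- lesionconn:::latent_correlation(spec, "patient")
  roles <- spec$network_roles
  expect_lt(cc_p[roles[["thalamic"]], roles[["precuneus"]]],
            cc_c[roles[["thalamic"]], roles[["precuneus"]]])
  expect_gt(cc_p[roles[["DMN"]], roles[["FEN"]]],
            cc_c[roles[["DMN"]], roles[["FEN"]]])
  # both remain valid correlation matrices
  expect_gt(min(eigen(cc_p, symmetric = TRUE)$values), 0)
  expect_equal(diag(cc_p), rep(1, spec$n_networks))
})
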