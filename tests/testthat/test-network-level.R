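make_part <- function(labels, lesion = integer(0)) {
  network_partition(labels, lesion_rois = lesion)
}

test_that("block means reproduce constructed within/between structure", {
  labels <- c(1, 1, 1, 2, 2, 2)
  z <- matrix(0.2, 6, 6)
  for (g in list(1:3, 4:6)) z[g, g] <- 1.0
  diag(z) <- NA
  bm <- block_means(z, make_part(labels))
  expect_equal(unname(diag(unclass(bm))), c(1, 1))
  expect_equal(unclass(bm)[1, 2], 0.2)

  # permutation of ROI order leaves the block matrix unchanged
  perm <- c(4, 1, 5, 2, 6, 3)
  bm2 <- block_means(z[perm, perm], make_part(labels[perm]))
  expect_equal(unclass(bm2), unclass(bm))
})

test_that("block means and lesion profiles match brute-force enumeration", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    k <- sample(2:4, 1)
    labels <- sample(rep_len(seq_len(k), n))
    lesion <- sample(n, 2)
    z <- random_symmetric(n)
    diag(z) <- NA
    part <- make_part(labels, lesion)
    bm <- block_means(z, part, exclude_lesion = FALSE)
    # oracle: loop every unordered pair
    acc <- array(0, c(k, k)); cnt <- array(0, c(k, k))
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- labels[i]; b <- labels[j]
        acc[a, b] <- acc[a, b] + z[i, j]; cnt[a, b] <- cnt[a, b] + 1
        if (a != b) { acc[b, a] <- acc[b, a] + z[i, j]; cnt[b, a] <- cnt[b, a] + 1 }
      }
    }
    oracle <- acc / cnt
    oracle[cnt == 0] <- NA
    expect_equal(unclass(bm), oracle, tolerance = 1e-12, ignore_attr = TRUE)

    lp <- lesion_profile(z, part)
    for (g in seq_len(k)) {
      targets <- setdiff(which(labels == g), lesion)
      exp_val <- if (length(targets) == 0) NA_real_
                 else mean(z[lesion, targets])
      expect_equal(unname(lp[g]), exp_val, tolerance = 1e-12)
    }
  }
})

test_that("segregation formula is exact and translation invariant", {
  labels <- rep(1:2, each = 3)
  z <- matrix(0.2, 6, 6)
  for (g in list(1:3, 4:6)) z[g, g] <- 1.0
  diag(z) <- NA
  bm <- block_means(z, make_part(labels))
  expect_equal(segregation(bm), 0.8)

  z_same <- matrix(0.5, 6, 6); diag(z_same) <- NA
  expect_equal(segregation(block_means(z_same, make_part(labels))), 0)

  # adding a constant to every edge shifts within and between equally
  bm_shift <- block_means(z + 3, make_part(labels))
  expect_equal(segregation(bm_shift), 0.8, tolerance = 1e-12)

  # singleton network: undefined diagonal, segregation errors
  bad <- block_means(z, make_part(c(1, 1, 1, 2, 2, 3)))
  expect_error(segregation(bad), "singleton")
})

test_that("lesion profile peaks where the lesion is coupled", {
  labels <- rep(1:3, each = 4)
  z <- matrix(0, 12, 12)
  z[1, 2:4] <- z[2:4, 1] <- 1  # lesion ROI 1 coupled only to network 1
  diag(z) <- NA
  lp <- lesion_profile(z, make_part(labels, lesion = 1))
  expect_identical(unname(which.max(lp)), 1L)
  z0 <- matrix(0, 12, 12); diag(z0) <- NA
  expect_equal(unname(lesion_profile(z0, make_part(labels, 1))),
               rep(0, 3))
  expect_error(lesion_profile(z, make_part(labels)), "empty lesion")
})

test_that("a 16-network contrast matrix has 120 unique pairwise cells", {
  set.seed(21)
  k <- 16
  blocks <- lapply(1:12, function(i) {
    m <- random_symmetric(k) + diag(k)
    dimnames(m) <- list(paste0("n", 1:k), paste0("n", 1:k))
    structure(m, class = c("block_matrix", "matrix"))
  })
  groups <- rep(c("control", "patient"), c(8, 4))
  sexes <- rep(c("M", "F"), 6)
  res <- network_contrast_matrix(blocks, groups, sexes)
  expect_identical(sum(upper.tri(res$t_mat)), 120L)
  expect_identical(res$families$offdiag, 120)
  expect_true(all(is.finite(res$t_mat)))
})

test_that("contrast matrix is calibrated under the null", {
  set.seed(22)
  k <- 6
  n_cohorts <- 400
  hits <- 0; cells <- 0
  for (c_idx in seq_len(n_cohorts)) {
    blocks <- lapply(1:14, function(i) {
      m <- random_symmetric(k)
      structure(m, class = c("block_matrix", "matrix"))
    })
    groups <- rep(c("control", "patient"), c(10, 4))
    res <- network_contrast_matrix(blocks, groups)
    p_up <- res$p_mat[upper.tri(res$p_mat)]
    hits <- hits + sum(p_up < 0.05)
    cells <- cells + length(p_up)
  }
  expect_lt(abs(hits / cells - 0.05), 0.02)
})

test_that("degenerate sex covariate is dropped with a warning", {
  set.seed(23)
  blocks <- lapply(1:10, function(i) {
    structure(random_symmetric(4), class = c("block_matrix", "matrix"))
  })
  groups <- rep(c("control", "patient"), c(6, 4))
  expect_warning(
    network_contrast_matrix(blocks, groups, sex = rep("M", 10)),
    "degenerate")
})
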