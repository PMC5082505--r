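test_that("percentile binarization keeps exactly the top-ranked edges", {
  z <- matrix(0, 4, 4)
  z[upper.tri(z)] <- c(0.1, 0.5, 0.3, 0.9, 0.7, 0.2)
  z <- z + t(z); diag(z) <- NA
  adj <- binarize_at_percentile(z, 50)
  expect_identical(attr(adj, "n_edges"), 3L)
  kept <- z[upper.tri(z)][unclass(adj)[upper.tri(adj)] == 1]
  expect_setequal(kept, c(0.9, 0.7, 0.5))

  full <- binarize_at_percentile(z, 0)
  expect_identical(attr(full, "n_edges"), 6L)

  set.seed(30)
  big <- random_symmetric(120); diag(big) <- NA
  sparse <- binarize_at_percentile(big, 99)
  expect_identical(attr(sparse, "n_edges"), 71L)  # round(0.01 * 7140)
  expect_identical(sum(unclass(sparse)) / 2, 71)

  expect_error(binarize_at_percentile(matrix(1, 4, 4), 50), "all edge")
})

test_that("tie handling matches retained edge counts across subjects", {
  set.seed(31)
  for (p in c(85, 92, 99)) {
    counts <- vapply(1:5, function(i) {
      z <- random_symmetric(40)
      z[upper.tri(z)] <- round(z[upper.tri(z)], 1)  # force ties
      z[lower.tri(z)] <- t(z)[lower.tri(z)]
      diag(z) <- NA
      attr(binarize_at_percentile(z, p), "n_edges")
    }, integer(1))
    expect_identical(length(unique(counts)), 1L)
  }
})

test_that("clustering and efficiency match hand-computed graphs", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(global_clustering(tri), 1)
  expect_equal(global_efficiency(tri), 1)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(global_clustering(star), 0)

  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(global_efficiency(k4), 1)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)

  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1
  expect_equal(global_efficiency(two_edges), 4 / 12)
})

test_that("graph metrics equal brute-force oracles on random graphs", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.7))
    expect_equal(global_clustering(adj), brute_clustering(adj),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(adj), brute_efficiency(adj),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to node relabeling", {
  set.seed(33)
  adj <- random_adjacency(12, 0.3)
  perm <- sample(12)
  padj <- adj[perm, perm]
  expect_equal(global_clustering(padj), global_clustering(adj))
  expect_equal(global_efficiency(padj), global_efficiency(adj))
  expect_equal(isolate_fraction(padj), isolate_fraction(adj))
})

test_that("efficiency never decreases when edges are added", {
  set.seed(34)
  adj <- random_adjacency(10, 0.15)
  e_prev <- global_efficiency(adj)
  empty <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
  for (r in sample(nrow(empty), min(10, nrow(empty)))) {
    adj[empty[r, 1], empty[r, 2]] <- adj[empty[r, 2], empty[r, 1]] <- 1L
    e_new <- global_efficiency(adj)
    expect_gte(e_new, e_prev - 1e-12)
    e_prev <- e_new
  }
})

test_that("small-world index and isolates behave as defined", {
  expect_equal(small_world_index(1, 1), 1)
  expect_equal(small_world_index(0.5, 0.4), 0.2)
  expect_equal(small_world_index(0, 0.9), 0)

  empty <- matrix(0L, 5, 5)
  expect_equal(isolate_fraction(empty), 1)
  expect_equal(isolate_fraction(matrix(1, 4, 4) - diag(4)), 0)
  one_iso <- matrix(0L, 4, 4)
  one_iso[1:3, 1:3] <- 1L; diag(one_iso) <- 0L
  expect_equal(isolate_fraction(one_iso), 0.25)
})

test_that("the threshold sweep covers the full range with shrinking graphs", {
  set.seed(35)
  z <- random_symmetric(30); diag(z) <- NA
  sweep <- metric_sweep(z)
  expect_identical(nrow(sweep), 15L)
  expect_identical(sweep$percentile, 85:99)
  expect_true(all(diff(sweep$n_edges) < 0))
  expect_true(all(sweep$clustering >= 0 & sweep$clustering <= 1))
  expect_true(all(sweep$small_world ==
                    sweep$clustering * sweep$efficiency))
})
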