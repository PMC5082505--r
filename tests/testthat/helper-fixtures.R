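# Small shared fixtures, built in code at test time.

# Desk-scale-but-tiny cohort specification: 24 ROIs in 8 networks, short
# series, all four named network roles present.
tiny_spec <- function(...) {
  # one-ROI lesion set: excluding it from its 3-ROI host network must not
  # create a singleton block
  cohort_spec(n_rois = 24, partition_sizes = rep(3L, 8L), n_volumes = 80,
              lesion_rois = 1L, ...)
}

# White-noise (null) specification: no latent structure at all.
null_spec <- function(n_rois = 40, n_volumes = 148) {
  cohort_spec(n_rois = n_rois,
              partition_sizes = rep(n_rois %/% 8, 8L),
              n_volumes = n_volumes,
              within_coupling = 0, global_coupling = 0, noise_sd = 1,
              base_rho = 0, alpha_lesion = 0, delta_within = 0,
              delta_tp = 0, delta_df = 0)
}

sim_ar1 <- function(n, rho) {
  x <- numeric(n)
  innov <- rnorm(n)
  x[1] <- innov[1]
  for (t in 2:n) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * innov[t]
  x
}

# Independent brute-force graph oracles (triple enumeration and
# Floyd-Warshall), deliberately naive.
brute_clustering <- function(adj) {
  n <- nrow(adj)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    c_i[i] <- 2 * links / (k * (k - 1))
  }
  mean(c_i)
}

brute_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

random_adjacency <- function(n, p_edge) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p_edge)
  a + t(a)
}

random_symmetric <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- rnorm(n * (n - 1) / 2)
  m + t(m)
}
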