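# Network-level aggregation of edge statistics: block means, segregation,
# lesion connectivity profiles, group contrast matrix.

conn_z <- function(conn) {
  if (inherits(conn, "connectivity_matrix")) conn$z else as.matrix(conn)
}

#' Within- and between-network block means of a connectivity matrix
#'
#' Cell (k, l) is the mean edge Z over unique ROI pairs with one ROI in
#' network k and one in network l; diagonal cells average the unique
#' within-network pairs (i < j), so the connectivity matrix diagonal never
#' contributes. Lesion ROIs are excluded from their host network by default
#' so lesion effects do not leak into network blocks (they are summarized
#' separately by [lesion_profile()]). Singleton networks have an undefined
#' (NA) diagonal cell.
#'
#' @param conn `connectivity_matrix` or plain symmetric matrix.
#' @param partition a [network_partition()].
#' @param exclude_lesion drop lesion ROIs from their networks (default
#'   `TRUE`).
#' @return object of class `block_matrix`: K x K symmetric matrix with
#'   network names, attribute `n_pairs` giving per-cell pair counts.
#' @export
block_means <- function(conn, partition, exclude_lesion = TRUE) {
  z <- conn_z(conn)
  labels <- partition$labels
  stopifnot(length(labels) == nrow(z))
  if (exclude_lesion && length(partition$lesion_rois) > 0) {
    labels[partition$lesion_rois] <- NA_integer_
  }
  k <- partition$n_networks
  out <- matrix(NA_real_, k, k,
                dimnames = list(partition$network_names,
                                partition$network_names))
  n_pairs <- matrix(0L, k, k)
  idx_by_net <- lapply(seq_len(k), function(g) which(!is.na(labels) & labels == g))
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- idx_by_net[[a]]; ib <- idx_by_net[[b]]
      if (a == b) {
        if (length(ia) < 2) next  # singleton: undefined, stays NA
        vals <- z[ia, ia][upper.tri(diag(length(ia)))]
      } else {
        if (length(ia) == 0 || length(ib) == 0) next
        vals <- as.vector(z[ia, ib])
      }
      out[a, b] <- out[b, a] <- mean(vals)
      n_pairs[a, b] <- n_pairs[b, a] <- length(vals)
    }
  }
  structure(out, n_pairs = n_pairs, class = c("block_matrix", "matrix"))
}

#' Network segregation of a block matrix
#'
#' Mean of the leading-diagonal (within-network) cells minus the mean of
#' the off-diagonal (between-network) cells. Because the block matrix is
#' symmetric, averaging the upper triangle equals averaging all
#' off-diagonal cells.
#'
#' @param block a `block_matrix` from [block_means()].
#' @return scalar segregation S.
#' @export
segregation <- function(block) {
  b <- unclass(block)
  if (anyNA(diag(b))) stop("undefined diagonal cell(s): singleton network")
  mean(diag(b)) - mean(b[upper.tri(b)])
}

#' Mean connectivity between the lesion ROIs and each network
#'
#' Entry k is the mean edge Z over all pairs (lesion ROI, non-lesion ROI of
#' network k); pairs internal to the lesion set are excluded.
#'
#' @inheritParams block_means
#' @return named length-K vector.
#' @export
lesion_profile <- function(conn, partition) {
  z <- conn_z(conn)
  lesion <- partition$lesion_rois
  if (length(lesion) == 0) stop("empty lesion ROI set")
  labels <- partition$labels
  out <- numeric(partition$n_networks)
  names(out) <- partition$network_names
  for (k in seq_len(partition$n_networks)) {
    targets <- setdiff(which(labels == k), lesion)
    out[k] <- if (length(targets) == 0) NA_real_
              else mean(z[lesion, targets, drop = FALSE])
  }
  out
}

#' Group contrast matrix over network blocks
#'
#' For every block cell, tests the patient-minus-control difference across
#' subjects with [pooled_t_covariate()] (sex as nuisance covariate when
#' supplied and non-degenerate). Bonferroni families follow the analysis
#' design: the K(K-1)/2 unique between-network cells form one family, the K
#' diagonal cells another, and (when lesion profiles are supplied) the K
#' lesion-row tests a third. The mask codes 0 = not significant,
#' 1 = p < alpha uncorrected, 2 = survives Bonferroni within its family.
#'
#' @param block_list per-subject `block_matrix` objects.
#' @param groups per-subject group labels (`"control"`/`"patient"`).
#' @param sex optional per-subject sex labels.
#' @param alpha uncorrected significance level (default 0.05).
#' @param lesion_profiles optional subjects x K matrix of
#'   [lesion_profile()] vectors.
#' @param families named list overriding Bonferroni family sizes
#'   (`offdiag`, `diag`, `lesion`).
#' @return list with `t_mat`, `p_mat`, `mask` (K x K), and when lesion
#'   profiles are given `lesion_t`, `lesion_p`, `lesion_mask`.
#' @export
network_contrast_matrix <- function(block_list, groups, sex = NULL,
                                    alpha = 0.05, lesion_profiles = NULL,
                                    families = NULL) {
  stopifnot(length(block_list) == length(groups))
  g <- as.integer(groups == "patient")
  stopifnot(sum(g) >= 3, sum(1 - g) >= 3)
  if (!is.null(sex) && length(unique(sex)) < 2) {
    warning("degenerate covariate (single sex); dropped")
    sex <- NULL
  }
  k <- nrow(block_list[[1]])
  fam <- list(offdiag = k * (k - 1) / 2, diag = k, lesion = k)
  if (!is.null(families)) fam[names(families)] <- families
  nm <- dimnames(block_list[[1]])[[1]]
  t_mat <- p_mat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k)) {
    for (b in a:k) {
      vals <- vapply(block_list, function(bm) unclass(bm)[a, b], numeric(1))
      if (anyNA(vals)) next
      res <- pooled_t_covariate(vals, g, sex)
      t_mat[a, b] <- t_mat[b, a] <- res$statistic
      p_mat[a, b] <- p_mat[b, a] <- res$p_two_tailed
    }
  }
  mask <- matrix(0L, k, k, dimnames = list(nm, nm))
  mask[!is.na(p_mat) & p_mat < alpha] <- 1L
  off <- upper.tri(p_mat) | lower.tri(p_mat)
  mask[off & !is.na(p_mat) &
         bonferroni_adjust(p_mat, fam$offdiag) < alpha] <- 2L
  di <- diag(k) == 1
  adj_diag <- bonferroni_adjust(p_mat, fam$diag)
  mask[di & !is.na(p_mat) & adj_diag < alpha] <- 2L
  out <- list(t_mat = t_mat, p_mat = p_mat, mask = mask, alpha = alpha,
              families = fam)
  if (!is.null(lesion_profiles)) {
    lesion_profiles <- as.matrix(lesion_profiles)
    stopifnot(nrow(lesion_profiles) == length(groups))
    lt <- lp <- rep(NA_real_, ncol(lesion_profiles))
    names(lt) <- names(lp) <- colnames(lesion_profiles)
    for (j in seq_len(ncol(lesion_profiles))) {
      vals <- lesion_profiles[, j]
      if (anyNA(vals)) next
      res <- pooled_t_covariate(vals, g, sex)
      lt[j] <- res$statistic
      lp[j] <- res$p_two_tailed
    }
    lmask <- integer(length(lp))
    lmask[!is.na(lp) & lp < alpha] <- 1L
    lmask[!is.na(lp) & bonferroni_adjust(lp, fam$lesion) < alpha] <- 2L
    out$lesion_t <- lt
    out$lesion_p <- lp
    out$lesion_mask <- lmask
  }
  out
}
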