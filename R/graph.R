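# Percentile-thresholded graph summaries of the connectome.

#' Binarize a connectivity matrix at a percentile threshold
#'
#' Keeps the edges whose Z exceeds the P-th percentile of the off-diagonal
#' upper-triangle values, i.e. the top (100 - P)% of connections, so the
#' retained edge count — and hence mean degree — is matched exactly across
#' subjects: the target count is `round((1 - P/100) * N(N-1)/2)`, enforced
#' by rank with ties broken by the fixed total order (Z descending, then
#' row, then column index).
#'
#' Note the direction: P = 99 is a *sparse* graph (top 1% of edges kept).
#' The literal "top P% of values" reading is available as `P' = 100 - P`.
#'
#' @param conn `connectivity_matrix` or symmetric matrix.
#' @param percentile P in \[0, 100).
#' @return object of class `adjacency`: binary symmetric N x N matrix with
#'   zero diagonal; attributes `percentile` and `n_edges`.
#' @export
binarize_at_percentile <- function(conn, percentile) {
  stopifnot(percentile >= 0, percentile < 100)
  z <- conn_z(conn)
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[ut]
  if (max(vals) - min(vals) < 1e-15) {
    stop("all edge values equal: no meaningful ranking")
  }
  m <- nrow(ut)
  n_keep <- as.integer(round((1 - percentile / 100) * m))
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_keep)]
  adj <- matrix(0L, n, n, dimnames = dimnames(z))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(adj, percentile = percentile, n_edges = n_keep,
            class = c("adjacency", "matrix"))
}

#' Global clustering coefficient
#'
#' Nodal clustering is the fraction of a node's neighbor pairs that are
#' themselves connected, \eqn{c_i = 2 T_i / (k_i (k_i - 1))} with
#' \eqn{T_i} the number of triangles through node i; nodes of degree < 2
#' (including isolates) contribute 0. The global value is the mean over
#' all nodes.
#'
#' @param adj binary symmetric adjacency with zero diagonal.
#' @return C in \[0, 1\].
#' @export
global_clustering <- function(adj) {
  a <- unclass(adj)
  storage.mode(a) <- "double"
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)  # 2 * triangles per node
  c_i <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(c_i)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' disconnected pairs contributing zero. Path lengths come from
#' breadth-first search on the binary graph.
#'
#' @inheritParams global_clustering
#' @return E in \[0, 1\].
#' @export
global_efficiency <- function(adj) {
  a <- unclass(adj)
  n <- nrow(a)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Small-worldness approximated as clustering times efficiency
#'
#' Small-worldness is classically the ratio of clustering to characteristic
#' path length; with efficiency inversely related to path length it is
#' approximated here as the product C * E.
#'
#' @param clustering,efficiency values in \[0, 1\].
#' @return C * E.
#' @export
small_world_index <- function(clustering, efficiency) {
  stopifnot(clustering >= 0, clustering <= 1,
            efficiency >= 0, efficiency <= 1)
  clustering * efficiency
}

#' Fraction of isolated nodes
#'
#' @inheritParams global_clustering
#' @return proportion of nodes with degree zero.
#' @export
isolate_fraction <- function(adj) {
  a <- unclass(adj)
  mean(rowSums(a) == 0)
}

#' Graph metric sweep over percentile thresholds
#'
#' Binarizes the connectivity matrix at each threshold and tabulates global
#' clustering, global efficiency, small-worldness, isolate fraction and
#' retained edge count.
#'
#' @param conn `connectivity_matrix` or symmetric matrix.
#' @param p_range percentile thresholds (default 85 to 99 in steps of 1).
#' @return data.frame with one row per threshold: `percentile`,
#'   `clustering`, `efficiency`, `small_world`, `isolate_fraction`,
#'   `n_edges`.
#' @export
metric_sweep <- function(conn, p_range = 85:99) {
  rows <- lapply(p_range, function(p) {
    adj <- binarize_at_percentile(conn, p)
    c_val <- global_clustering(adj)
    e_val <- global_efficiency(adj)
    data.frame(percentile = p, clustering = c_val, efficiency = e_val,
               small_world = small_world_index(c_val, e_val),
               isolate_fraction = isolate_fraction(adj),
               n_edges = attr(adj, "n_edges"))
  })
  do.call(rbind, rows)
}
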