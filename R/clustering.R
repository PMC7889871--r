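# shared-nearest-neighbor graph from a cells x d embedding: k-NN by Euclidean
# distance, edge weight = fraction of shared neighbors among the k
snn_graph <- function(embedding, k_neighbors) {
  n <- nrow(embedding)
  d <- as.matrix(dist(embedding))
  # neighbor sets include the cell itself so identical points share all
  # neighbors
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k_neighbors + 1)])
  edges <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- unique(unlist(nb[nb[[i]]]))
    for (j in cand) {
      if (j > i) {
        w <- length(intersect(nb[[i]], nb[[j]])) / (k_neighbors + 1)
        edges[i, j] <- w
        edges[j, i] <- w
      }
    }
  }
  igraph::graph_from_adjacency_matrix(edges, mode = "undirected", weighted = TRUE)
}

#' Cluster cells into groups from a low-dimensional embedding
#'
#' Builds a shared-nearest-neighbor (SNN) graph from the k-nearest neighbors
#' of each cell in the embedding (edge weight = shared-neighbor fraction) and
#' partitions it with the Louvain community detection algorithm. When no
#' resolution is given, the number of groups is chosen by the eigenvalue-gap
#' of the Laplacian of a consensus matrix built from Louvain runs across a
#' sweep of resolution values.
#'
#' @param embedding Numeric matrix or data frame, cells x d (d >= 2), with
#'   cell names as rownames (or a `cell` first column).
#' @param k_neighbors Number of nearest neighbors for the SNN graph
#'   (default 20).
#' @param resolution Optional Louvain resolution; when `NULL` the consensus
#'   eigen-gap rule picks the group number.
#' @param resolutions Resolution sweep used when `resolution` is `NULL`.
#' @param seed Random seed for Louvain.
#' @return A `cell_grouping` tibble (cell, group).
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = NULL,
                          resolutions = c(0.4, 0.6, 0.8, 1, 1.2, 1.6), seed = 1) {
  if (is.data.frame(embedding)) {
    df <- as_tibble(embedding)
    if (is.character(df[[1]])) {
      cells <- df[[1]]
      embedding <- as.matrix(df[, -1])
      rownames(embedding) <- cells
    } else {
      embedding <- as.matrix(df)
    }
  }
  n <- nrow(embedding)
  if (ncol(embedding) < 2) abort("embedding must have at least 2 dimensions")
  if (n <= k_neighbors) {
    abort(sprintf("need more than k_neighbors + 1 = %d cells, got %d", k_neighbors + 1, n))
  }
  cells <- rownames(embedding) %||% paste0("cell", seq_len(n))
  # canonical processing order so the partition does not depend on how the
  # input rows happen to be sorted
  ord <- order(cells)
  embedding <- embedding[ord, , drop = FALSE]
  cells <- cells[ord]

  # all cells coincident: a single group, no graph needed
  if (all(dist(embedding) == 0)) {
    return(cell_grouping(cells, rep("1", n)))
  }

  g <- snn_graph(embedding, k_neighbors)
  louvain_at <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_louvain(g, resolution = res))
  }
  if (!is.null(resolution)) {
    memb <- louvain_at(resolution)
  } else {
    runs <- lapply(resolutions, louvain_at)
    consensus <- Reduce(`+`, lapply(runs, function(m) outer(m, m, "=="))) /
      length(runs)
    k_opt <- eigen_gap_count(consensus, prune = 0)
    # final labels: the sweep partition whose group count is closest to the
    # consensus choice (ties to the lower resolution)
    counts <- vapply(runs, function(m) length(unique(m)), integer(1))
    memb <- runs[[which.min(abs(counts - k_opt))]]
  }
  cell_grouping(cells, as.character(memb))
}

# number of clusters from the Laplacian eigenvalue spectrum of a (pruned)
# consensus co-assignment matrix: the count at the largest (or second
# largest) gap between consecutive ascending eigenvalues
eigen_gap_count <- function(consensus, prune = 0.3, use_second = FALSE,
                            k_max = nrow(consensus) - 1) {
  c_mat <- consensus
  c_mat[c_mat < prune] <- 0
  lap <- diag(rowSums(c_mat)) - c_mat
  ev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  gaps <- diff(ev)[seq_len(min(k_max, length(ev) - 1))]
  ord <- order(gaps, decreasing = TRUE)
  if (use_second && length(ord) > 1) ord[2] else ord[1]
}
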