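#' Smooth a network similarity matrix with a shared-nearest-neighbor graph
#'
#' Builds the SNN graph of pathways from their k nearest neighbors under the
#' similarity matrix, with k the rounded square root of the number of
#' pathways, weights it by the shared-neighbor fraction, and returns the
#' symmetrized product `Gs S`. Smoothing suppresses weak (noise-induced)
#' similarities and reinforces strong ones before manifold learning.
#'
#' @param s A [similarity_matrix()] (or symmetric matrix in [0, 1]).
#' @param k Number of nearest neighbors; default `round(sqrt(N))`.
#' @return Smoothed symmetric matrix with the same dimnames; attribute
#'   `snn_k` records k.
#' @export
snn_smooth <- function(s, k = NULL) {
  s <- unclass(s)
  n <- nrow(s)
  k <- k %||% max(1, round(sqrt(n)))
  # neighbor sets by decreasing similarity; a pathway is its own first
  # neighbor since the diagonal is maximal
  nb <- lapply(seq_len(n), function(i) order(s[i, ], decreasing = TRUE)[seq_len(k)])
  gs <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gs[i, j] <- length(intersect(nb[[i]], nb[[j]])) / k
    }
  }
  sm <- gs %*% s
  sm <- (sm + t(sm)) / 2
  dimnames(sm) <- dimnames(s)
  attr(sm, "snn_k") <- k
  sm
}

#' Embed signaling networks on a 2-D manifold
#'
#' UMAP embedding of pathways from a (smoothed) similarity matrix. Because
#' SNN smoothing rescales each pathway's row by its neighborhood mass, the
#' matrix is first normalized like a correlation,
#' `s_ij / sqrt(s_ii s_jj)`, and then converted to the distance
#' `1 - similarity`; pathways with identical communication networks are at
#' distance 0. Zero-distance pathways are one point of the underlying
#' metric space, so they are embedded once and share coordinates (layout
#' repulsion would otherwise separate exact duplicates arbitrarily). The
#' first two manifold dimensions are returned. Deterministic for a fixed
#' seed.
#'
#' @param s Smoothed similarity matrix (pathways x pathways, dimnames =
#'   pathway labels).
#' @param seed Random seed.
#' @param n_neighbors UMAP neighborhood size; defaults to the SNN k (or
#'   `round(sqrt(N))`), clipped to [2, N - 1].
#' @param min_dist UMAP minimum distance (default 0.3).
#' @return Tibble: `pathway`, `x`, `y` (class `manifold_embedding`).
#' @export
embed_manifold <- function(s, seed = 1, n_neighbors = NULL, min_dist = 0.3) {
  n <- nrow(s)
  if (n < 3) abort("need at least 3 pathways to embed")
  labels <- rownames(s) %||% paste0("pathway", seq_len(n))
  k <- n_neighbors %||% attr(s, "snn_k") %||% round(sqrt(n))
  k <- min(max(2, k), n - 1)
  s_raw <- unclass(s)
  scale_d <- sqrt(pmax(diag(s_raw), .Machine$double.eps))
  s_scaled <- s_raw / outer(scale_d, scale_d)
  d <- 1 - s_scaled
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  # collapse zero-distance pathways onto one representative point
  rep_of <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- reps[which(d[i, reps] < 1e-12)]
    if (length(hit) > 0) {
      rep_of[i] <- hit[1]
    } else {
      reps <- c(reps, i)
      rep_of[i] <- i
    }
  }
  if (length(reps) < 3) {
    abort("need at least 3 distinct pathway profiles to embed")
  }
  du <- d[reps, reps, drop = FALSE]
  ku <- min(k, length(reps) - 1)
  set.seed(seed)
  coords_u <- uwot::umap(
    as.dist(du),
    n_neighbors = ku, min_dist = min_dist, n_threads = 1,
    n_sgd_threads = 0
  )
  coords <- coords_u[match(rep_of, reps), , drop = FALSE]
  out <- tibble(pathway = labels, x = coords[, 1], y = coords[, 2])
  class(out) <- c("manifold_embedding", class(tibble()))
  out
}

#' Group pathways by consensus k-means with eigen-gap model selection
#'
#' Runs k-means on the 2-D embedding for each candidate group count, builds
#' the consensus co-assignment matrix across those runs, prunes entries
#' below `prune`, and picks the group count at the largest (or second
#' largest) gap of the consensus Laplacian eigenvalue spectrum. Final labels
#' come from k-means at the chosen count.
#'
#' @param emb A [embed_manifold()] tibble (or any tibble with `x`, `y`).
#' @param candidate_k Candidate group counts (default 2:10, clipped).
#' @param prune Consensus pruning threshold (default 0.3).
#' @param use_second Use the second largest eigen-gap.
#' @param seed Random seed for k-means.
#' @return The embedding tibble with a `group` factor column; attributes
#'   `n_groups` and `diagnostics` (consensus eigenvalues).
#' @export
group_pathways <- function(emb, candidate_k = 2:10, prune = 0.3,
                           use_second = FALSE, seed = 1) {
  pts <- as.matrix(emb[, c("x", "y")])
  n <- nrow(pts)
  if (nrow(unique(pts)) == 1) {
    warn("all embedded points coincide; assigning a single group")
    out <- emb
    out$group <- factor(rep(1, n))
    attr(out, "n_groups") <- 1L
    return(out)
  }
  candidate_k <- candidate_k[candidate_k < n & candidate_k >= 2]
  candidate_k <- candidate_k[candidate_k <= nrow(unique(pts))]
  if (length(candidate_k) == 0) abort("no feasible candidate group counts")
  set.seed(seed)
  runs <- lapply(candidate_k, function(k) {
    kmeans(pts, centers = k, nstart = 10)$cluster
  })
  consensus <- Reduce(`+`, lapply(runs, function(cl) outer(cl, cl, "=="))) /
    length(runs)
  n_groups <- eigen_gap_count(consensus, prune = prune, use_second = use_second,
    k_max = max(candidate_k)
  )
  set.seed(seed)
  final <- kmeans(pts, centers = min(n_groups, nrow(unique(pts))), nstart = 10)$cluster
  out <- emb
  out$group <- factor(final)
  attr(out, "n_groups") <- as.integer(n_groups)
  attr(out, "consensus") <- consensus
  out
}

#' Jointly embed and group signaling networks from multiple datasets
#'
#' Pools the networks of two or more datasets, computes their pairwise
#' functional or structural similarity, smooths it with the SNN graph,
#' embeds everything on one 2-D manifold and groups the points by consensus
#' k-means. Functional similarity requires all datasets to share the same
#' cell group composition; structural similarity does not.
#'
#' @param network_sets Named list of datasets, each a named list of
#'   `comm_network` objects.
#' @param kind `"functional"` or `"structural"`.
#' @param seed Random seed.
#' @param candidate_k,prune,use_second Passed to [group_pathways()].
#' @param ... Passed to [similarity_matrix()].
#' @return Tibble: `dataset`, `pathway`, `x`, `y`, `group`.
#' @export
joint_embed <- function(network_sets, kind = c("functional", "structural"),
                        seed = 1, candidate_k = 2:10, prune = 0.3,
                        use_second = FALSE, ...) {
  kind <- match.arg(kind)
  if (length(network_sets) < 2) abort("need at least 2 datasets to jointly embed")
  if (is.null(names(network_sets))) {
    names(network_sets) <- paste0("dataset", seq_along(network_sets))
  }
  nets <- list()
  tags <- list()
  for (ds in names(network_sets)) {
    for (pw in names(network_sets[[ds]])) {
      nets[[paste(ds, pw, sep = "/")]] <- network_sets[[ds]][[pw]]
      tags[[paste(ds, pw, sep = "/")]] <- c(ds, pw)
    }
  }
  if (kind == "functional") {
    group_sets <- unique(lapply(nets, function(nw) rownames(nw$adjacency)))
    if (length(group_sets) > 1) {
      abort("functional similarity requires the same cell group composition across datasets")
    }
  }
  s <- similarity_matrix(nets, kind = kind, ...)
  sm <- snn_smooth(s)
  emb <- embed_manifold(sm, seed = seed)
  emb$dataset <- vapply(emb$pathway, function(nm) tags[[nm]][1], character(1))
  emb$pathway <- vapply(emb$pathway, function(nm) tags[[nm]][2], character(1))
  emb <- emb[, c("dataset", "pathway", "x", "y")]
  grouped <- group_pathways(emb, candidate_k = candidate_k, prune = prune,
    use_second = use_second, seed = seed
  )
  attr(grouped, "similarity") <- s
  grouped
}

#' Distance between a shared pathway's positions in a joint embedding
#'
#' Euclidean distance between the two coordinate rows of the same pathway
#' from two datasets — large distances mark pathways whose communication
#' networks changed most between conditions.
#'
#' @param emb A [joint_embed()] tibble.
#' @param pathway Pathway label present in both datasets.
#' @param datasets Optional pair of dataset names (defaults to the first two
#'   carrying the pathway).
#' @return Non-negative scalar.
#' @export
pathway_distance <- function(emb, pathway, datasets = NULL) {
  rows <- emb[emb$pathway == pathway, , drop = FALSE]
  if (!is.null(datasets)) rows <- rows[rows$dataset %in% datasets, , drop = FALSE]
  if (nrow(rows) < 2) {
    abort(paste0("pathway ", pathway, " is not shared by two datasets"))
  }
  sqrt(sum((as.numeric(rows[1, c("x", "y")]) - as.numeric(rows[2, c("x", "y")]))^2))
}
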