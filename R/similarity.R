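#' Functional similarity of two signaling networks
#'
#' Jaccard similarity of the directed edge sets of two networks defined on
#' the same ordered cell groups: `|E(A) n E(B)| / |E(A) u E(B)|`. Identical
#' non-empty edge sets score 1, disjoint sets 0; two empty networks score 1
#' by convention. High functional similarity means the two pathways share
#' senders and receivers. The literal printed form that divides by the
#' symmetric difference (undefined for identical networks) is available via
#' `printed_form = TRUE`, guarded against zero denominators.
#'
#' @param net_a,net_b `comm_network` objects over identical group sets.
#' @param printed_form Use the symmetric-difference denominator.
#' @return Similarity in [0, 1] (unbounded under `printed_form`).
#' @export
functional_similarity <- function(net_a, net_b, printed_form = FALSE) {
  ga <- rownames(net_a$adjacency)
  gb <- rownames(net_b$adjacency)
  if (!identical(ga, gb)) {
    abort("functional similarity requires the same cell group composition")
  }
  ea <- which(net_a$adjacency > 0)
  eb <- which(net_b$adjacency > 0)
  inter <- length(intersect(ea, eb))
  uni <- length(union(ea, eb))
  if (printed_form) {
    denom <- uni - inter
    if (denom == 0) return(if (uni == 0) 1 else Inf)
    return(inter / denom)
  }
  if (uni == 0) return(1)
  inter / uni
}

# node-distance distributions of an undirected binarized graph: p_i(j) =
# fraction of the other N-1 nodes at shortest-path distance j from i, with
# disconnected pairs binned at diameter + 1; returns an N x n_bins matrix
distance_distributions <- function(adj, n_bins = NULL) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  finite <- d[is.finite(d) & d > 0]
  diam <- if (length(finite) > 0) max(finite) else 0
  d[!is.finite(d)] <- diam + 1
  n_bins <- n_bins %||% (diam + 1)
  p <- matrix(0, n, n_bins)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    for (j in seq_len(n_bins)) p[i, j] <- sum(di == j) / (n - 1)
  }
  list(p = p, diameter = diam)
}

# Jensen-Shannon divergence of N discrete distributions (rows); natural log
jsd_multi <- function(p) {
  n <- nrow(p)
  u <- colMeans(p)
  total <- 0
  for (i in seq_len(n)) {
    pos <- p[i, ] > 0
    total <- total + sum(p[i, pos] * log(p[i, pos] / u[pos]))
  }
  max(total / n, 0) # clamp -eps from floating point
}

jsd_two <- function(p, q) {
  len <- max(length(p), length(q))
  p <- c(p, rep(0, len - length(p)))
  q <- c(q, rep(0, len - length(q)))
  jsd_multi(rbind(p, q))
}

# network node dispersion: JSD of the node-distance distributions over
# log(diameter + 1); 0 when all distributions coincide or the graph is empty
nnd_value <- function(dd) {
  if (dd$diameter + 1 <= 1) return(0)
  jsd_multi(dd$p) / log(dd$diameter + 1)
}

# alpha-centrality distribution: x = (I - a A)^T-solve with exogenous ones,
# a = alpha_frac / spectral radius; normalized to sum 1
alpha_centrality_dist <- function(adj, alpha_frac = 0.9) {
  n <- nrow(adj)
  lam <- max(abs(eigen(adj, only.values = TRUE)$values))
  x <- if (lam == 0) {
    rep(1, n)
  } else {
    solve(diag(n) - (alpha_frac / lam) * t(adj), rep(1, n))
  }
  x <- abs(x)
  if (sum(x) == 0) rep(1 / n, n) else x / sum(x)
}

complement_adj <- function(adj) {
  comp <- 1 - adj
  diag(comp) <- 0
  comp
}

#' Structural dissimilarity of two signaling networks
#'
#' A topology-only distance built from three terms: (1) the Jensen-Shannon
#' divergence between the networks' average node-distance distributions,
#' (2) the difference of the square-rooted network node dispersions (the
#' JSD among each network's per-node distance distributions, normalized by
#' log(diameter + 1)), and (3) the JSD between alpha-centrality
#' distributions of the graphs and of their complements:
#' `D = w1 sqrt(JSD(u_A, u_B)/log 2) + w2 |sqrt(NND_A) - sqrt(NND_B)| +
#'  (w3/2) (sqrt(JSD(Pa_A, Pa_B)/log 2) + sqrt(JSD(Pa_Ac, Pa_Bc)/log 2))`.
#' Networks are binarized at `binarize_threshold` and treated as undirected;
#' disconnected node pairs are binned one past the diameter. `D(G, G) = 0`;
#' two empty networks give 0 by convention. Structural similarity is
#' `1 - D`.
#'
#' @param net_a,net_b `comm_network` objects (group sets need not match).
#' @param w1,w2,w3 Term weights summing to 1 (defaults 0.45/0.45/0.1).
#' @param binarize_threshold Edge present iff adjacency > threshold
#'   (default 0).
#' @param alpha_frac Alpha-centrality damping as a fraction of the inverse
#'   spectral radius (default 0.9).
#' @return Dissimilarity `D` in [0, 1].
#' @export
structural_dissimilarity <- function(net_a, net_b, w1 = 0.45, w2 = 0.45,
                                     w3 = 0.1, binarize_threshold = 0,
                                     alpha_frac = 0.9) {
  stopifnot(abs(w1 + w2 + w3 - 1) < 1e-9)
  adj_a <- 1 * ((net_a$adjacency + t(net_a$adjacency)) > binarize_threshold)
  adj_b <- 1 * ((net_b$adjacency + t(net_b$adjacency)) > binarize_threshold)
  diag(adj_a) <- 0
  diag(adj_b) <- 0
  if (sum(adj_a) == 0 && sum(adj_b) == 0) return(0)
  dd_a <- distance_distributions(adj_a)
  dd_b <- distance_distributions(adj_b)
  u_a <- colMeans(dd_a$p)
  u_b <- colMeans(dd_b$p)
  term1 <- sqrt(jsd_two(u_a, u_b) / log(2))
  term2 <- abs(sqrt(nnd_value(dd_a)) - sqrt(nnd_value(dd_b)))
  pa_a <- alpha_centrality_dist(adj_a, alpha_frac)
  pa_b <- alpha_centrality_dist(adj_b, alpha_frac)
  pc_a <- alpha_centrality_dist(complement_adj(adj_a), alpha_frac)
  pc_b <- alpha_centrality_dist(complement_adj(adj_b), alpha_frac)
  term3 <- (sqrt(jsd_two(pa_a, pa_b) / log(2)) +
    sqrt(jsd_two(pc_a, pc_b) / log(2))) / 2
  w1 * term1 + w2 * term2 + w3 * term3
}

#' Pairwise similarity matrix over a set of signaling networks
#'
#' @param networks Named list of `comm_network` objects (names become
#'   pathway labels).
#' @param kind `"functional"` (edge-set Jaccard; requires identical group
#'   sets) or `"structural"` (1 - topological dissimilarity).
#' @param ... Passed to [structural_dissimilarity()].
#' @return A symmetric `similarity_matrix` in [0, 1] with unit diagonal and
#'   a `kind` attribute.
#' @export
similarity_matrix <- function(networks, kind = c("functional", "structural"),
                              ...) {
  kind <- match.arg(kind)
  n <- length(networks)
  labels <- names(networks) %||% vapply(networks, `[[`, "", "pathway")
  s <- matrix(1, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s[i, j] <- s[j, i] <- if (kind == "functional") {
          functional_similarity(networks[[i]], networks[[j]])
        } else {
          1 - structural_dissimilarity(networks[[i]], networks[[j]], ...)
        }
      }
    }
  }
  structure(s, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}
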