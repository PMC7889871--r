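#' Centrality scores of a signaling network
#'
#' Computes, for each cell group in a weighted directed signaling network,
#' the four role measures: weighted out-degree (dominant senders), weighted
#' in-degree (dominant receivers), Freeman flow betweenness (gatekeepers /
#' mediators of communication flow) and Stephenson-Zelen information
#' centrality (influencers controlling information flow), plus optional
#' hub/authority/eigenvector/PageRank scores. Each measure is also min-max
#' scaled to [0, 1] as its relative importance across groups.
#'
#' @param net A `comm_network`.
#' @param extras Also compute hub, authority, eigenvector and PageRank
#'   scores (default `FALSE`).
#' @return Tibble with one row per group: raw measures and
#'   `<measure>_scaled` columns.
#' @export
centrality_scores <- function(net, extras = FALSE) {
  stopifnot(inherits(net, "comm_network"))
  a <- net$adjacency
  out <- tibble(
    group = rownames(a),
    out_degree = unname(rowSums(a)),
    in_degree = unname(colSums(a)),
    flow_betweenness = unname(flow_betweenness(net)),
    information_centrality = unname(information_centrality(net))
  )
  if (extras) {
    g <- igraph::graph_from_adjacency_matrix(a, mode = "directed", weighted = TRUE)
    out$hub <- as.numeric(igraph::hits_scores(g)$hub)
    out$authority <- as.numeric(igraph::hits_scores(g)$authority)
    out$eigen <- as.numeric(igraph::eigen_centrality(g, directed = FALSE)$vector)
    out$pagerank <- as.numeric(igraph::page_rank(g)$vector)
  }
  measures <- setdiff(names(out), "group")
  for (msr in measures) {
    out[[paste0(msr, "_scaled")]] <- minmax_scale(out[[msr]])
  }
  out
}

#' Freeman flow betweenness
#'
#' For each group v, the sum over ordered pairs (s, t), s != t != v, of the
#' reduction in maximum flow from s to t when v is removed from the weighted
#' directed network — the group's capacity as gatekeeper of communication
#' flow. The normalized variant divides by the total max-flow not involving v.
#'
#' @param net A `comm_network`.
#' @param normalized Divide each score by the total pairwise max-flow
#'   excluding the vertex (default `FALSE`).
#' @return Named numeric vector over groups.
#' @export
flow_betweenness <- function(net, normalized = FALSE) {
  a <- net$adjacency
  k <- nrow(a)
  grp <- rownames(a)
  scores <- setNames(numeric(k), grp)
  if (k < 3 || sum(a) == 0) return(scores)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "directed", weighted = TRUE)
  mf <- matrix(0, k, k)
  for (s in seq_len(k)) {
    for (t in seq_len(k)) {
      if (s != t) {
        mf[s, t] <- igraph::max_flow(g, s, t, capacity = igraph::E(g)$weight)$value
      }
    }
  }
  for (v in seq_len(k)) {
    gv <- igraph::delete_vertices(g, v)
    others <- setdiff(seq_len(k), v)
    tot <- 0
    red <- 0
    for (si in seq_along(others)) {
      for (ti in seq_along(others)) {
        if (si != ti) {
          f_full <- mf[others[si], others[ti]]
          f_cut <- igraph::max_flow(gv, si, ti,
            capacity = igraph::E(gv)$weight
          )$value
          red <- red + (f_full - f_cut)
          tot <- tot + f_full
        }
      }
    }
    scores[v] <- if (normalized) {
      if (tot > 0) red / tot else 0
    } else {
      red
    }
  }
  scores
}

#' Stephenson-Zelen information centrality
#'
#' Computed on the symmetrized weighted graph `(A + t(A)) / 2`. For each
#' connected component with at least two vertices, with `B = L + J`
#' (Laplacian plus all-ones) and `C = B^{-1}`, the centrality of vertex i is
#' `1 / (C_ii + (trace(C) - 2 R_i) / n)` where `R_i` is the i-th row sum of
#' `C`. Isolated vertices score 0 by convention.
#'
#' @param net A `comm_network`.
#' @return Named numeric vector over groups.
#' @export
information_centrality <- function(net) {
  a <- (net$adjacency + t(net$adjacency)) / 2
  diag(a) <- 0
  k <- nrow(a)
  scores <- setNames(numeric(k), rownames(a))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected", weighted = TRUE)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    nc <- length(members)
    if (nc < 2) next # isolated vertex: 0
    sub <- a[members, members, drop = FALSE]
    lap <- diag(rowSums(sub)) - sub
    b <- lap + 1
    cmat <- solve(b)
    tr <- sum(diag(cmat))
    rs <- rowSums(cmat)
    scores[members] <- 1 / (diag(cmat) + (tr - 2 * rs) / nc)
  }
  scores
}

#' Dominant signaling roles per measure
#'
#' Labels the group(s) attaining the (tie-aware) maximum of each centrality
#' measure with the corresponding role: out-degree -> sender, in-degree ->
#' receiver, flow betweenness -> mediator, information centrality ->
#' influencer.
#'
#' @param scores A [centrality_scores()] tibble.
#' @param tol Relative tolerance for ties on the maximum.
#' @return Tibble: `role`, `measure`, `group`.
#' @export
role_summary <- function(scores, tol = 1e-9) {
  roles <- c(
    sender = "out_degree", receiver = "in_degree",
    mediator = "flow_betweenness", influencer = "information_centrality"
  )
  out <- list()
  for (rl in names(roles)) {
    v <- scores[[roles[[rl]]]]
    mx <- max(v)
    if (mx <= 0) next
    winners <- scores$group[v >= mx * (1 - tol)]
    out[[rl]] <- tibble(role = rl, measure = roles[[rl]], group = winners)
  }
  if (length(out) == 0) {
    warn("all centrality scores are zero; no roles assigned")
    return(tibble(role = character(), measure = character(), group = character()))
  }
  bind_rows(out)
}
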