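# independent brute-force oracles, deliberately coded from first principles
# and not sharing code paths with the package implementation

# trimean oracle: explicit type-7 quantile interpolation on a sorted copy
oracle_trimean <- function(x) {
  s <- sort(x)
  n <- length(s)
  q_at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  0.5 * q_at(0.5) + 0.25 * (q_at(0.25) + q_at(0.75))
}

# mass-action score oracle: direct scalar arithmetic with per-group
# agonist/antagonist means (0 = no cofactor)
oracle_probability <- function(lig, rec, ag_i = 0, ag_j = 0, an_i = 0,
                               an_j = 0, ra = 0, ri = 0,
                               kh = 0.5, hill_n = 1, pop = 1) {
  gm <- function(v) if (any(v == 0)) 0 else prod(v)^(1 / length(v))
  l <- gm(lig)
  r <- gm(rec) * (1 + ra) / (1 + ri)
  lr <- l * r
  hill <- lr^hill_n / (kh^hill_n + lr^hill_n)
  hill * (1 + ag_i / (kh + ag_i)) * (1 + ag_j / (kh + ag_j)) *
    (kh / (kh + an_i)) * (kh / (kh + an_j)) * pop
}

# Floyd-Warshall shortest paths on a binary undirected adjacency
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_jsd <- function(p_rows) {
  u <- colMeans(p_rows)
  total <- 0
  for (i in seq_len(nrow(p_rows))) {
    for (j in seq_len(ncol(p_rows))) {
      if (p_rows[i, j] > 0) {
        total <- total + p_rows[i, j] * log(p_rows[i, j] / u[j])
      }
    }
  }
  max(total / nrow(p_rows), 0)
}

# alpha-centrality by truncated power series (independent of solve())
oracle_alpha_centrality <- function(adj, alpha_frac = 0.9, iters = 2000) {
  n <- nrow(adj)
  ev <- eigen(adj, only.values = TRUE)$values
  lam <- max(abs(ev))
  if (lam == 0) return(rep(1 / n, n))
  a <- alpha_frac / lam
  at <- t(adj)
  x <- rep(1, n)
  term <- rep(1, n)
  for (it in seq_len(iters)) {
    term <- a * (at %*% term)
    x <- x + as.numeric(term)
    if (max(abs(term)) < 1e-14) break
  }
  x <- abs(x)
  x / sum(x)
}

# full structural dissimilarity oracle for binary undirected adjacencies
oracle_structural_d <- function(adj_a, adj_b, w1 = 0.45, w2 = 0.45, w3 = 0.1,
                                alpha_frac = 0.9) {
  dist_distr <- function(adj) {
    n <- nrow(adj)
    d <- oracle_distances(adj)
    finite <- d[is.finite(d) & d > 0]
    diam <- if (length(finite) > 0) max(finite) else 0
    d[!is.finite(d)] <- diam + 1
    bins <- diam + 1
    p <- matrix(0, n, bins)
    for (i in seq_len(n)) {
      for (j in seq_len(bins)) p[i, j] <- sum(d[i, -i] == j) / (n - 1)
    }
    list(p = p, diam = diam)
  }
  pad <- function(v, len) c(v, rep(0, len - length(v)))
  if (sum(adj_a) == 0 && sum(adj_b) == 0) return(0)
  da <- dist_distr(adj_a)
  db_ <- dist_distr(adj_b)
  ua <- colMeans(da$p)
  ub <- colMeans(db_$p)
  len <- max(length(ua), length(ub))
  t1 <- sqrt(oracle_jsd(rbind(pad(ua, len), pad(ub, len))) / log(2))
  nnd <- function(dd) {
    if (dd$diam + 1 <= 1) return(0)
    oracle_jsd(dd$p) / log(dd$diam + 1)
  }
  t2 <- abs(sqrt(nnd(da)) - sqrt(nnd(db_)))
  comp <- function(adj) {
    cm <- 1 - adj
    diag(cm) <- 0
    cm
  }
  pa_a <- oracle_alpha_centrality(adj_a, alpha_frac)
  pa_b <- oracle_alpha_centrality(adj_b, alpha_frac)
  pc_a <- oracle_alpha_centrality(comp(adj_a), alpha_frac)
  pc_b <- oracle_alpha_centrality(comp(adj_b), alpha_frac)
  t3 <- (sqrt(oracle_jsd(rbind(pa_a, pa_b)) / log(2)) +
    sqrt(oracle_jsd(rbind(pc_a, pc_b)) / log(2))) / 2
  unname(w1 * t1 + w2 * t2 + w3 * t3)
}

# information centrality oracle: harmonic mean of pairwise information
# I_ij = 1/(c_ii + c_jj - 2 c_ij) with I_ii = 1/c_ii, computed per component
oracle_information_centrality <- function(adj) {
  adj <- (adj + t(adj)) / 2
  diag(adj) <- 0
  n <- nrow(adj)
  scores <- numeric(n)
  # connected components by reachability over positive edges
  reach <- oracle_distances(1 * (adj > 0))
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- which(is.finite(reach[i, ]))
    assigned[members] <- TRUE
    if (length(members) < 2) next
    sub <- adj[members, members, drop = FALSE]
    b <- diag(rowSums(sub)) - sub + 1
    cm <- solve(b)
    nc <- length(members)
    for (mi in seq_len(nc)) {
      # 1/I_ij = c_ii + c_jj - 2 c_ij; the self term is 0 (infinite
      # self-information), so the harmonic sum runs over j != i only
      inv_sum <- 0
      for (mj in seq_len(nc)) {
        if (mj != mi) inv_sum <- inv_sum + cm[mi, mi] + cm[mj, mj] - 2 * cm[mi, mj]
      }
      scores[members[mi]] <- 1 / (inv_sum / nc)
    }
  }
  scores
}

# all non-isomorphic undirected graphs on n nodes (as adjacency matrices)
all_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  n_edges <- ncol(pairs)
  reps <- list()
  igs <- list()
  for (code in 0:(2^n_edges - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_edges)]
    adj <- matrix(0, n, n)
    for (e in seq_len(n_edges)) {
      if (bits[e] == 1) {
        adj[pairs[1, e], pairs[2, e]] <- 1
        adj[pairs[2, e], pairs[1, e]] <- 1
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    iso <- any(vapply(igs, function(h) igraph::isomorphic(g, h), logical(1)))
    if (!iso) {
      reps[[length(reps) + 1]] <- adj
      igs[[length(igs) + 1]] <- g
    }
  }
  reps
}
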