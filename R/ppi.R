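#' Smooth expression profiles over a protein-protein interaction network
#'
#' Optionally projects per-cell gene expression onto a protein-protein
#' interaction (PPI) network by a random walk with restart: the smoothed
#' profile is the stationary solution `f = r (I - (1 - r) W)^{-1} f0` with
#' `W` the column-normalized PPI adjacency and `r` the restart probability.
#' Genes absent from the PPI pass through unchanged, and each cell's total
#' mass over PPI genes is preserved, so smoothing redistributes rather than
#' creates signal. With `restart_prob = 1` the transform is the identity.
#'
#' @param expr Genes x cells matrix.
#' @param ppi_edges Data frame with columns `from`, `to` and optionally
#'   `weight` (undirected edges over gene symbols). An empty edge list is an
#'   identity transform.
#' @param restart_prob Restart probability in (0, 1]; default 0.5.
#' @return A matrix of the same shape and dimnames as `expr`.
#' @export
project_on_ppi <- function(expr, ppi_edges, restart_prob = 0.5) {
  stopifnot(restart_prob > 0, restart_prob <= 1)
  if (is.null(ppi_edges) || nrow(ppi_edges) == 0 || restart_prob == 1) {
    return(expr)
  }
  ppi_edges <- as_tibble(ppi_edges)
  if (!"weight" %in% names(ppi_edges)) ppi_edges$weight <- 1
  genes <- intersect(
    unique(c(ppi_edges$from, ppi_edges$to)),
    rownames(expr)
  )
  keep <- ppi_edges$from %in% genes & ppi_edges$to %in% genes
  ppi_edges <- ppi_edges[keep, , drop = FALSE]
  if (nrow(ppi_edges) == 0) return(expr)

  p <- length(genes)
  a <- matrix(0, p, p, dimnames = list(genes, genes))
  for (e in seq_len(nrow(ppi_edges))) {
    i <- ppi_edges$from[e]
    j <- ppi_edges$to[e]
    a[i, j] <- a[i, j] + ppi_edges$weight[e]
    if (i != j) a[j, i] <- a[j, i] + ppi_edges$weight[e]
  }
  deg <- colSums(a)
  w <- sweep(a, 2, pmax(deg, .Machine$double.eps), "/")
  # stationary RWR operator applied to every cell at once
  op <- restart_prob * solve(diag(p) - (1 - restart_prob) * w)
  sub <- as.matrix(expr[genes, , drop = FALSE])
  smoothed <- op %*% sub
  smoothed[smoothed < 0] <- 0
  # preserve each cell's total signaling-gene mass
  mass0 <- colSums(sub)
  mass1 <- colSums(smoothed)
  scale <- ifelse(mass1 > 0, mass0 / mass1, 1)
  smoothed <- sweep(smoothed, 2, scale, "*")
  out <- as.matrix(expr)
  out[genes, ] <- smoothed
  out
}
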