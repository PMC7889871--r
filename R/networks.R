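#' Aggregate significant communications into per-pathway networks
#'
#' A pathway's signaling network is the K x K weighted directed adjacency
#' whose entries sum the communication probabilities of the pathway's
#' significant ligand-receptor pairs (entries with p >= alpha contribute 0).
#' Pathways whose adjacency is all-zero are dropped.
#'
#' @param result A `comm_result`.
#' @param alpha Significance level; defaults to the inference alpha.
#' @return Named list of `comm_network` objects (one per retained pathway),
#'   each holding `pathway`, `adjacency` (K x K matrix) and `pair_ids`.
#' @export
aggregate_pathways <- function(result, alpha = NULL) {
  alpha <- alpha %||% result$params$alpha
  k <- length(result$groups)
  nets <- list()
  for (pw in unique(result$pairs$pathway)) {
    ids <- result$pairs$id[result$pairs$pathway == pw]
    adj <- matrix(0, k, k, dimnames = list(result$groups, result$groups))
    for (id in ids) {
      mask <- result$pval[, , id] < alpha
      adj <- adj + result$prob[, , id] * mask
    }
    if (any(adj > 0)) {
      nets[[pw]] <- comm_network(pw, adj, ids)
    }
  }
  nets
}

#' Construct a signaling network
#'
#' @param pathway Pathway label.
#' @param adjacency K x K non-negative matrix with group dimnames.
#' @param pair_ids Ids of contributing ligand-receptor pairs.
#' @return A `comm_network`.
#' @export
comm_network <- function(pathway, adjacency, pair_ids = character(0)) {
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == ncol(adjacency), all(adjacency >= 0))
  if (is.null(rownames(adjacency))) {
    grp <- paste0("G", seq_len(nrow(adjacency)))
    dimnames(adjacency) <- list(grp, grp)
  }
  structure(
    list(pathway = pathway, adjacency = adjacency, pair_ids = pair_ids),
    class = "comm_network"
  )
}

#' @method print comm_network
#' @export
print.comm_network <- function(x, ...) {
  cat(sprintf(
    "<comm_network> pathway %s: %d groups, %d positive edges, flow %.4g\n",
    x$pathway, nrow(x$adjacency), sum(x$adjacency > 0), information_flow(x)
  ))
  invisible(x)
}

#' @method tidy comm_network
#' @export
tidy.comm_network <- function(x, ...) {
  grp <- rownames(x$adjacency)
  tibble(
    pathway = x$pathway,
    source = factor(rep(grp, times = length(grp)), levels = grp),
    target = factor(rep(grp, each = length(grp)), levels = grp),
    weight = as.vector(x$adjacency)
  ) |>
    filter(.data$weight > 0)
}

#' Total information flow of a signaling network
#'
#' The sum of communication probabilities over all ordered pairs of cell
#' groups — the overall strength of a pathway, used to rank pathways within
#' and across datasets.
#'
#' @param net A `comm_network`.
#' @return Non-negative scalar.
#' @export
information_flow <- function(net) {
  stopifnot(inherits(net, "comm_network"))
  sum(net$adjacency)
}

#' Relative contribution of each ligand-receptor pair to a pathway
#'
#' The ratio of each pair's total significant communication probability to
#' the pathway's total; fractions sum to 1 when the pathway carries flow.
#'
#' @param result A `comm_result`.
#' @param pathway Pathway label.
#' @param alpha Significance level; defaults to the inference alpha.
#' @return Tibble: `id`, `flow`, `contribution`.
#' @export
pair_contribution <- function(result, pathway, alpha = NULL) {
  alpha <- alpha %||% result$params$alpha
  ids <- result$pairs$id[result$pairs$pathway == pathway]
  if (length(ids) == 0) abort(paste0("pathway not in result: ", pathway))
  flow <- unname(vapply(ids, function(id) {
    sum(result$prob[, , id] * (result$pval[, , id] < alpha))
  }, numeric(1)))
  total <- sum(flow)
  if (total == 0) {
    warn(paste0("pathway ", pathway, " has zero flow; contributions set to 0"))
    contribution <- rep(0, length(ids))
  } else {
    contribution <- flow / total
  }
  tibble(id = ids, flow = flow, contribution = contribution)
}
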