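#' Tukey's trimean
#'
#' Robust location estimate `0.5 * Q2 + 0.25 * (Q1 + Q3)` with quartiles by
#' linear interpolation (type-7). The trimean of a cell group's expression is
#' zero unless the gene is expressed in more than a quarter of the group's
#' cells, which makes group summaries robust to dropout noise.
#'
#' @param values Non-empty numeric vector.
#' @return The trimean.
#' @examples
#' trimean(1:5) # 3
#' @export
trimean <- function(values) {
  if (length(values) == 0) abort("trimean of an empty vector")
  q <- quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  0.5 * q[2] + 0.25 * (q[1] + q[3])
}

# vectorized trimean over matrix rows (type-7 interpolation on sorted rows)
row_trimean <- function(x) {
  n <- ncol(x)
  if (n == 1) return(x[, 1])
  s <- t(apply(x, 1, sort.int, method = "quick"))
  h <- (n - 1) * c(0.25, 0.5, 0.75) + 1
  lo <- floor(h)
  hi <- ceiling(h)
  q <- function(k) s[, lo[k]] + (h[k] - lo[k]) * (s[, hi[k]] - s[, lo[k]])
  0.5 * q(2) + 0.25 * (q(1) + q(3))
}

#' Trimean expression per gene per cell group
#'
#' @param expr Genes x cells matrix.
#' @param grouping A `cell_grouping`, factor or label vector.
#' @param genes Optional subset of genes to summarize.
#' @return Tibble: `gene`, `group`, `expression` (the group trimean).
#' @export
group_expression <- function(expr, grouping, genes = NULL) {
  labels <- align_grouping(expr, grouping)
  if (any(table(labels) == 0)) abort("grouping contains an empty group")
  genes <- genes %||% rownames(expr)
  em <- group_expression_matrix(expr, labels, genes)
  as_tibble(em, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "group", values_to = "expression") |>
    mutate(group = factor(.data$group, levels = levels(labels)))
}

# genes x K matrix of group trimeans
group_expression_matrix <- function(expr, labels, genes) {
  x <- as.matrix(expr[genes, , drop = FALSE])
  em <- matrix(0, length(genes), nlevels(labels),
    dimnames = list(genes, levels(labels))
  )
  for (grp in levels(labels)) {
    em[, grp] <- row_trimean(x[, labels == grp, drop = FALSE])
  }
  em
}

#' Expression of a multi-subunit complex
#'
#' The complex level is the geometric mean of its subunit levels, so zero
#' expression of any required subunit inactivates the whole complex.
#' Subunits missing from the expression data are treated as zero.
#'
#' @param values Named numeric vector of gene expression values.
#' @param subunits Character vector of subunit genes.
#' @return The complex expression level.
#' @export
complex_expression <- function(values, subunits) {
  v <- values[subunits]
  v[is.na(v)] <- 0
  geometric_mean(unname(v))
}

#' Receptor level modulated by co-stimulatory / co-inhibitory receptors
#'
#' Linear modulation of the receptor complex level:
#' `R * (1 + RA) / (1 + RI)` with `RA`/`RI` the mean expression of the
#' co-stimulatory / co-inhibitory receptor sets.
#'
#' @param r_core Receptor complex expression (geometric mean of subunits).
#' @param ra_mean,ri_mean Mean expression of the co-stimulatory and
#'   co-inhibitory gene sets (0 when the set is empty).
#' @return Modulated receptor level.
#' @export
modulated_receptor <- function(r_core, ra_mean = 0, ri_mean = 0) {
  stopifnot(r_core >= 0, ra_mean >= 0, ri_mean >= 0)
  r_core * (1 + ra_mean) / (1 + ri_mean)
}

#' Inference parameters for the mass-action communication model
#'
#' @param kh Half-saturation constant of the Hill function; 0.5 by default,
#'   matching input expression normalized to a [0, 1] range.
#' @param hill_n Hill cooperativity exponent applied to the ligand-receptor
#'   product (denominator `kh^n + (L R)^n`); default 1.
#' @param permutations Number of label permutations `M` (default 100).
#' @param alpha Significance level for the permutation test (default 0.05).
#' @param population_size Multiply each probability by `n_i n_j / n^2` to
#'   account for group abundance (default `TRUE`; disable for
#'   sorting-enriched data).
#' @param min_cells Groups smaller than this are excluded with a warning
#'   (default 10).
#' @param de_alpha Significance level of the over-expression pre-filter.
#' @param strictness Interaction eligibility rule: `"any"` flagged subunit
#'   (default) or `"all"` subunits of ligand or receptor flagged.
#' @param tail Permutation p-value tail; `"upper"` (default) counts
#'   permuted probabilities at or above the observed one, so small p marks
#'   strong interactions. `"lower"` is the mirrored count.
#' @param max_expression Warn when the matrix maximum exceeds this bound
#'   (default 10), suggesting the data is not on the [0, 1] scale `kh`
#'   assumes.
#' @param seed Random seed for the permutation test.
#' @return A list of class `comm_params`.
#' @export
comm_params <- function(kh = 0.5, hill_n = 1, permutations = 100,
                        alpha = 0.05, population_size = TRUE, min_cells = 10,
                        de_alpha = 0.05, strictness = c("any", "all"),
                        tail = c("upper", "lower"), max_expression = 10,
                        seed = 1L) {
  stopifnot(kh > 0, hill_n > 0, permutations >= 1, alpha > 0, alpha < 1)
  p <- list(
    kh = kh, hill_n = hill_n, permutations = as.integer(permutations),
    alpha = alpha, population_size = isTRUE(population_size),
    min_cells = min_cells, de_alpha = de_alpha,
    strictness = match.arg(strictness), tail = match.arg(tail),
    max_expression = max_expression, seed = as.integer(seed)
  )
  class(p) <- "comm_params"
  p
}

# mass-action machinery: precompute per-interaction gene indices against a
# fixed gene vector so the permutation loop only redoes trimeans and
# arithmetic
prepare_pairs <- function(db, genes) {
  missing_sub <- setdiff(
    unique(unlist(c(db$ligand_subunits, db$receptor_subunits))), genes
  )
  if (length(missing_sub) > 0) {
    warn(paste0(
      "subunit gene(s) absent from expression matrix treated as zero: ",
      paste(head(missing_sub, 10), collapse = ", ")
    ))
  }
  lapply(seq_len(nrow(db)), function(i) {
    list(
      id = db$id[i],
      pathway = db$pathway[i],
      lig = match(db$ligand_subunits[[i]], genes), # NA = absent = zero
      rec = match(db$receptor_subunits[[i]], genes),
      ag = match(intersect(db$agonists[[i]], genes), genes),
      an = match(intersect(db$antagonists[[i]], genes), genes),
      rs = match(intersect(db$co_stimulatory[[i]], genes), genes),
      ri = match(intersect(db$co_inhibitory[[i]], genes), genes)
    )
  })
}

# geometric mean of EM rows per group; any NA (absent) or zero subunit gives 0
complex_cols <- function(em, rows) {
  if (anyNA(rows)) return(rep(0, ncol(em)))
  sub <- em[rows, , drop = FALSE]
  out <- exp(colMeans(log(pmax(sub, .Machine$double.xmin))))
  out[apply(sub == 0, 2, any)] <- 0
  out
}

mean_cols <- function(em, rows) {
  if (length(rows) == 0) return(rep(0, ncol(em)))
  colMeans(em[rows, , drop = FALSE])
}

# K x K x N mass-action score array from a genes x K trimean matrix
probability_array <- function(em, pairs, sizes, params) {
  k <- ncol(em)
  n_pairs <- length(pairs)
  kh <- params$kh
  hn <- params$hill_n
  pop <- if (params$population_size) {
    outer(sizes, sizes) / sum(sizes)^2
  } else {
    matrix(1, k, k)
  }
  p <- array(0, dim = c(k, k, n_pairs))
  for (idx in seq_len(n_pairs)) {
    pr <- pairs[[idx]]
    l_i <- complex_cols(em, pr$lig)
    r_j <- complex_cols(em, pr$rec) *
      (1 + mean_cols(em, pr$rs)) / (1 + mean_cols(em, pr$ri))
    lr <- outer(l_i, r_j)
    hill <- lr^hn / (kh^hn + lr^hn)
    ag <- mean_cols(em, pr$ag)
    an <- mean_cols(em, pr$an)
    ag_f <- 1 + ag / (kh + ag)
    an_f <- kh / (kh + an)
    p[, , idx] <- hill * outer(ag_f, ag_f) * outer(an_f, an_f) * pop
  }
  dimnames(p) <- list(colnames(em), colnames(em), vapply(pairs, `[[`, "", "id"))
  p
}

#' Infer intercellular communication probabilities and significance
#'
#' The full inference pipeline: (a) flag over-expressed signaling genes per
#' group (one-sided Wilcoxon, [identify_overexpressed()]); (b) summarize
#' group expression by the trimean; (c) score each eligible ligand-receptor
#' interaction between every ordered pair of groups with a mass-action Hill
#' model on the ligand and receptor complex levels, modulated by soluble
#' agonists/antagonists, co-stimulatory/co-inhibitory receptors, and
#' (optionally) the product of group population fractions; (d) assess
#' significance by recomputing the score under `M` random permutations of
#' the cell group labels. The permutation p-value of an entry is the
#' fraction of permutations whose recomputed score reaches the observed one.
#'
#' @param expr Genes x cells expression matrix.
#' @param grouping A `cell_grouping`, factor or label vector over cells.
#' @param db An `lr_database`.
#' @param params A [comm_params()] list.
#' @param de Optional precomputed [identify_overexpressed()] table; `NULL`
#'   computes it, `NA` disables the pre-filter (all interactions eligible).
#' @param ppi_edges Optional PPI edge list for [project_on_ppi()] smoothing
#'   (off by default).
#' @param restart_prob Restart probability for PPI smoothing.
#' @return A `comm_result`: list with `prob` and `pval` (K x K x N arrays),
#'   `pairs` (tibble id/pathway/eligible), `groups`, `group_sizes`, `params`.
#'   Use [tidy()] for the long table of scores, and
#'   [aggregate_pathways()] for per-pathway networks.
#' @export
infer_communication <- function(expr, grouping, db, params = comm_params(),
                                de = NULL, ppi_edges = NULL,
                                restart_prob = 0.5) {
  stopifnot(inherits(db, "lr_database"), inherits(params, "comm_params"))
  labels <- align_grouping(expr, grouping)
  sizes <- table(labels)
  small <- names(sizes)[sizes < params$min_cells]
  if (length(small) > 0) {
    warn(paste0(
      "excluding group(s) below min_cells = ", params$min_cells, ": ",
      paste(small, collapse = ", ")
    ))
    keep <- !(labels %in% small)
    expr <- expr[, keep, drop = FALSE]
    labels <- droplevels(labels[keep])
    sizes <- table(labels)
  }
  if (nlevels(labels) < 2) abort("need at least 2 cell groups for inference")
  mx <- max(expr)
  if (mx > params$max_expression) {
    warn(sprintf(
      "matrix maximum %.3g exceeds %.3g; the Hill model assumes expression roughly in [0, 1] - consider rescaling",
      mx, params$max_expression
    ))
  }
  if (!is.null(ppi_edges)) {
    expr <- project_on_ppi(expr, ppi_edges, restart_prob)
  }

  if (is.null(de)) {
    de <- identify_overexpressed(expr, labels, db, alpha = params$de_alpha)
  }
  eligible <- if (length(de) == 1 && is.na(de[1])) {
    rep(TRUE, nrow(db))
  } else {
    eligible_interactions(db, de, params$strictness)
  }

  genes_needed <- intersect(gene_universe(db), rownames(expr))
  x <- as.matrix(expr[genes_needed, , drop = FALSE])
  pairs_all <- prepare_pairs(db, genes_needed)
  pairs <- pairs_all[eligible]
  k <- nlevels(labels)
  n_all <- nrow(db)
  sizes_num <- as.numeric(sizes)

  prob <- array(0, dim = c(k, k, n_all),
    dimnames = list(levels(labels), levels(labels), db$id)
  )
  pval <- array(1, dim = dim(prob), dimnames = dimnames(prob))

  if (length(pairs) > 0) {
    em_obs <- group_expression_matrix(x, labels, genes_needed)
    p_obs <- probability_array(em_obs, pairs, sizes_num, params)
    set.seed(params$seed)
    counts <- array(0, dim = dim(p_obs))
    for (m in seq_len(params$permutations)) {
      perm <- sample.int(length(labels))
      em_m <- group_expression_matrix(x[, perm, drop = FALSE], labels, genes_needed)
      p_m <- probability_array(em_m, pairs, sizes_num, params)
      counts <- counts + if (params$tail == "upper") (p_m >= p_obs) else (p_m <= p_obs)
    }
    pv <- counts / params$permutations
    prob[, , eligible] <- p_obs
    pval[, , eligible] <- pv
  }

  structure(
    list(
      prob = prob, pval = pval,
      pairs = tibble(id = db$id, pathway = db$pathway, eligible = eligible),
      groups = levels(labels),
      group_sizes = setNames(as.integer(sizes), names(sizes)),
      params = params, de = if (is.data.frame(de)) de else NULL
    ),
    class = "comm_result"
  )
}

#' @method print comm_result
#' @export
print.comm_result <- function(x, ...) {
  sig <- sum(x$prob > 0 & x$pval < x$params$alpha)
  cat(sprintf(
    "<comm_result> %d groups x %d interactions (%d eligible); %d significant entries at alpha = %g\n",
    length(x$groups), nrow(x$pairs), sum(x$pairs$eligible), sig, x$params$alpha
  ))
  invisible(x)
}

#' Tidy a communication inference result
#'
#' @param x A `comm_result`.
#' @param ... Unused.
#' @return Long tibble: `source`, `target`, `id`, `pathway`, `prob`, `pval`,
#'   `significant`.
#' @method tidy comm_result
#' @export
tidy.comm_result <- function(x, ...) {
  k <- length(x$groups)
  n <- nrow(x$pairs)
  tibble(
    source = factor(rep(x$groups, times = k * n), levels = x$groups),
    target = factor(rep(rep(x$groups, each = k), times = n), levels = x$groups),
    id = rep(x$pairs$id, each = k * k),
    pathway = rep(x$pairs$pathway, each = k * k),
    prob = as.vector(x$prob),
    pval = as.vector(x$pval)
  ) |>
    mutate(significant = .data$prob > 0 & .data$pval < x$params$alpha)
}

#' @method glance comm_result
#' @export
glance.comm_result <- function(x, ...) {
  td <- tidy(x)
  sig <- td[td$significant, ]
  tibble(
    n_groups = length(x$groups),
    n_interactions = nrow(x$pairs),
    n_eligible = sum(x$pairs$eligible),
    n_significant_entries = nrow(sig),
    n_significant_pairs = length(unique(sig$id)),
    n_significant_pathways = length(unique(sig$pathway)),
    total_flow = sum(sig$prob)
  )
}

#' Significant (source, target, interaction) communications
#'
#' @param result A `comm_result`.
#' @param alpha Significance level; defaults to the one used at inference.
#' @return Tibble of significant entries, strongest first.
#' @export
significant_communications <- function(result, alpha = NULL) {
  alpha <- alpha %||% result$params$alpha
  tidy(result) |>
    filter(.data$prob > 0, .data$pval < alpha) |>
    arrange(desc(.data$prob))
}
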