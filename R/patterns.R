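#' Outgoing / incoming signaling role matrix
#'
#' Collapses the significant communication tensor onto a cell-groups x
#' signals matrix: the outgoing matrix sums each group's significant
#' probabilities over targets (how strongly the group sends each signal),
#' the incoming matrix sums over sources (how strongly it receives). Signals
#' are pathways when `by = "pathway"` (default) or individual ligand-receptor
#' pairs.
#'
#' @param result A `comm_result`.
#' @param direction `"outgoing"` or `"incoming"`.
#' @param by Aggregate signals by `"pathway"` or `"pair"`.
#' @param alpha Significance level; defaults to the inference alpha.
#' @return A `role_matrix`: numeric matrix (groups x signals) with a
#'   `direction` attribute.
#' @export
build_role_matrix <- function(result, direction = c("outgoing", "incoming"),
                              by = c("pathway", "pair"), alpha = NULL) {
  direction <- match.arg(direction)
  by <- match.arg(by)
  alpha <- alpha %||% result$params$alpha
  k <- length(result$groups)
  masked <- result$prob * (result$pval < alpha)
  margin <- if (direction == "outgoing") 1 else 2
  per_pair <- apply(masked, c(margin, 3), sum) # groups x pairs
  if (by == "pair") {
    pj <- per_pair
  } else {
    pws <- unique(result$pairs$pathway)
    pj <- matrix(0, k, length(pws), dimnames = list(result$groups, pws))
    for (pw in pws) {
      cols <- which(result$pairs$pathway == pw)
      pj[, pw] <- rowSums(per_pair[, cols, drop = FALSE])
    }
  }
  rownames(pj) <- result$groups
  structure(pj, direction = direction, class = c("role_matrix", "matrix", "array"))
}

# Frobenius NMF by multiplicative updates (Lee-Seung); one run
nmf_run <- function(v, r, max_iter = 2000, tol = 1e-10) {
  eps <- .Machine$double.eps
  k <- nrow(v)
  n <- ncol(v)
  w <- matrix(runif(k * r), k, r) * sqrt(mean(v) / r + eps)
  h <- matrix(runif(r * n), r, n) * sqrt(mean(v) / r + eps)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (t(w) %*% v) / (t(w) %*% w %*% h + eps)
    w <- w * (v %*% t(h)) / (w %*% (h %*% t(h)) + eps)
    if (it %% 20 == 0) {
      err <- sum((v - w %*% h)^2)
      if (err_prev - err < tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(w = w, h = h, error = sqrt(sum((v - w %*% h)^2)))
}

#' Non-negative matrix factorization of a role matrix
#'
#' Frobenius-norm NMF `Pj ~ W H` with `W` (groups x R) the cell-loading and
#' `H` (R x signals) the signaling-loading matrix; each of the R components
#' is a communication pattern. The best of `n_runs` random non-negative
#' initializations (by reconstruction error) is kept. All-zero rows/columns
#' are removed before factorization and re-inserted as zero loadings.
#'
#' @param pj A [build_role_matrix()] result (or any non-negative matrix).
#' @param r Number of patterns; must be < min(groups, signals).
#' @param n_runs Random restarts (default 10).
#' @param seed Random seed.
#' @return A `pattern_decomposition`: list with `w`, `h`, `r`, `error`,
#'   `direction`.
#' @export
nmf_factorize <- function(pj, r, n_runs = 10, seed = 1) {
  pj <- as.matrix(pj)
  stopifnot(all(pj >= 0))
  keep_row <- rowSums(pj) > 0
  keep_col <- colSums(pj) > 0
  v <- pj[keep_row, keep_col, drop = FALSE]
  if (r >= min(dim(v))) {
    abort(sprintf(
      "number of patterns r = %d must be below min(groups, signals) = %d",
      r, min(dim(v))
    ))
  }
  set.seed(seed)
  best <- NULL
  for (run in seq_len(n_runs)) {
    fit <- nmf_run(v, r)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  w <- matrix(0, nrow(pj), r, dimnames = list(rownames(pj), paste0("pattern", seq_len(r))))
  h <- matrix(0, r, ncol(pj), dimnames = list(paste0("pattern", seq_len(r)), colnames(pj)))
  w[keep_row, ] <- best$w
  h[, keep_col] <- best$h
  structure(
    list(
      w = w, h = h, r = r, error = best$error,
      direction = attr(pj, "direction") %||% "outgoing"
    ),
    class = "pattern_decomposition"
  )
}

#' @method print pattern_decomposition
#' @export
print.pattern_decomposition <- function(x, ...) {
  cat(sprintf(
    "<pattern_decomposition> %d %s patterns over %d groups x %d signals (error %.4g)\n",
    x$r, x$direction, nrow(x$w), ncol(x$h), x$error
  ))
  invisible(x)
}

#' @method tidy pattern_decomposition
#' @export
tidy.pattern_decomposition <- function(x, ...) {
  bind_rows(
    as_tibble(x$w, rownames = "element") |>
      tidyr::pivot_longer(-"element", names_to = "pattern", values_to = "loading") |>
      mutate(matrix = "cell"),
    as_tibble(t(x$h), rownames = "element") |>
      tidyr::pivot_longer(-"element", names_to = "pattern", values_to = "loading") |>
      mutate(matrix = "signaling")
  )
}

#' Select the number of communication patterns
#'
#' For each candidate pattern count R, runs `n_runs` random-restart
#' factorizations, assigns each group to its dominant pattern, and builds a
#' consensus co-assignment matrix across runs. Stability is measured by the
#' cophenetic correlation of the consensus hierarchical clustering and the
#' mean silhouette width of its R-cluster cut. The selected R is the largest
#' value before either metric first drops by more than `drop_tol` below its
#' running maximum (the silhouette is usually the sensitive one: the
#' cophenetic correlation of a near-binary consensus stays close to 1 even
#' past the stable rank); when no drop occurs the default of 5 patterns
#' (clipped to the candidate range) is used.
#'
#' @param pj A role matrix.
#' @param candidate_r Candidate pattern counts (default 2:10, clipped below
#'   min(dim)).
#' @param n_runs Factorizations per candidate.
#' @param seed Random seed.
#' @param drop_tol Drop tolerance (default 0.025).
#' @param default_r Fallback when no drop is detected (default 5).
#' @return List: `r` (selected), `diagnostics` tibble (candidate R,
#'   cophenetic, silhouette).
#' @export
select_pattern_number <- function(pj, candidate_r = 2:10, n_runs = 10,
                                  seed = 1, drop_tol = 0.025, default_r = 5) {
  pj <- as.matrix(pj)
  keep_row <- rowSums(pj) > 0
  keep_col <- colSums(pj) > 0
  v <- pj[keep_row, keep_col, drop = FALSE]
  candidate_r <- candidate_r[candidate_r < min(dim(v)) & candidate_r >= 2]
  if (length(candidate_r) == 0) abort("no feasible candidate pattern counts")
  k <- nrow(v)
  coph <- sil <- numeric(length(candidate_r))
  for (ci in seq_along(candidate_r)) {
    r <- candidate_r[ci]
    set.seed(seed + r)
    consensus <- matrix(0, k, k)
    for (run in seq_len(n_runs)) {
      fit <- nmf_run(v, r)
      assign <- max.col(fit$w, ties.method = "first")
      consensus <- consensus + outer(assign, assign, "==")
    }
    consensus <- consensus / n_runs
    d <- as.dist(1 - consensus)
    if (max(d) == 0) {
      coph[ci] <- 1
      sil[ci] <- 1
      next
    }
    hc <- hclust(d, method = "average")
    cd <- cophenetic(hc)
    coph[ci] <- if (sd(cd) == 0) 1 else cor(d, cd)
    cl <- cutree(hc, k = min(r, k - 1))
    sil[ci] <- if (length(unique(cl)) < 2) {
      1
    } else {
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }
  }
  run_max_c <- cummax(coph)
  run_max_s <- cummax(sil)
  drop_at <- which(
    run_max_c - coph > drop_tol | run_max_s - sil > drop_tol
  )
  selected <- if (length(drop_at) > 0 && drop_at[1] > 1) {
    candidate_r[drop_at[1] - 1]
  } else {
    min(max(candidate_r), max(min(candidate_r), default_r))
  }
  list(
    r = selected,
    diagnostics = tibble(r = candidate_r, cophenetic = coph, silhouette = sil)
  )
}

#' Threshold pattern loadings for display
#'
#' Min-max normalizes each row of W and each column of H to [0, 1], then
#' zeroes entries below the mode's cutoff: 0.5 in `"alluvial"` mode (each
#' group/signal keeps only its dominant pattern association) or `1/R` in
#' `"dotplot"` mode (a looser cut that keeps secondary associations).
#' All-equal positive rows/columns normalize to all-1.
#'
#' @param dec A `pattern_decomposition`.
#' @param mode `"alluvial"` or `"dotplot"`.
#' @return The decomposition with thresholded `w` and `h`.
#' @export
threshold_loadings <- function(dec, mode = c("alluvial", "dotplot")) {
  mode <- match.arg(mode)
  cutoff <- if (mode == "alluvial") 0.5 else 1 / dec$r
  w <- t(apply(dec$w, 1, minmax_scale))
  h <- apply(dec$h, 2, minmax_scale)
  if (dec$r == 1) {
    w <- matrix(w, ncol = 1, dimnames = dimnames(dec$w))
    h <- matrix(h, nrow = 1, dimnames = dimnames(dec$h))
  }
  w[w < cutoff] <- 0
  h[h < cutoff] <- 0
  dimnames(w) <- dimnames(dec$w)
  dimnames(h) <- dimnames(dec$h)
  out <- dec
  out$w <- w
  out$h <- h
  out
}

#' Contribution score of each cell group to each signal
#'
#' The product `W H` of the pattern loadings: how much each group
#' contributes to each pathway through the latent patterns. Optionally the
#' dotplot-thresholded loadings are multiplied instead, which restricts
#' scores to the enriched group/signal associations.
#'
#' @param dec A `pattern_decomposition`.
#' @param threshold Apply dotplot thresholding first (default `FALSE`).
#' @return Groups x signals matrix.
#' @export
contribution_scores <- function(dec, threshold = FALSE) {
  d <- if (threshold) threshold_loadings(dec, "dotplot") else dec
  d$w %*% d$h
}
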