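#' Compare overall information flow between two datasets
#'
#' Ranks the pathways of two inferred network sets by the difference of
#' their total information flow and classifies each shared or
#' dataset-specific pathway as turned off, decreased, unchanged, increased
#' or turned on in the second dataset.
#'
#' @param nets_a,nets_b Named lists of `comm_network` objects (e.g. from
#'   [aggregate_pathways()]) for conditions A and B.
#' @param tol Absolute flow below which a pathway counts as off
#'   (default 1e-9).
#' @param rel_tol Relative tolerance under which flows count as unchanged
#'   (default 0.05).
#' @return Tibble ranked by signed flow difference (B - A, descending):
#'   `pathway`, `flow_a`, `flow_b`, `difference`, `category`, `rank`.
#' @export
compare_information_flow <- function(nets_a, nets_b, tol = 1e-9,
                                     rel_tol = 0.05) {
  flows <- function(nets) {
    if (length(nets) == 0) return(setNames(numeric(0), character(0)))
    setNames(vapply(nets, information_flow, numeric(1)), names(nets))
  }
  fa <- flows(nets_a)
  fb <- flows(nets_b)
  pws <- union(names(fa), names(fb))
  flow_a <- ifelse(pws %in% names(fa), fa[pws], 0)
  flow_b <- ifelse(pws %in% names(fb), fb[pws], 0)
  diffs <- flow_b - flow_a
  category <- dplyr::case_when(
    flow_b <= tol & flow_a > tol ~ "off_in_B",
    flow_a <= tol & flow_b > tol ~ "on_in_B",
    abs(diffs) <= rel_tol * pmax(flow_a, flow_b) ~ "unchanged",
    diffs > 0 ~ "increased",
    TRUE ~ "decreased"
  )
  tibble(
    pathway = pws, flow_a = unname(flow_a), flow_b = unname(flow_b),
    difference = unname(diffs), category = category
  ) |>
    arrange(desc(.data$difference)) |>
    mutate(rank = row_number())
}

#' False-positive rate from partially identified multi-subunit complexes
#'
#' Scores a list of single-gene ligand-receptor predictions (as produced by
#' tools that ignore complex structure) against a ground-truth database with
#' multi-subunit complexes. A prediction is a false positive when its
#' (ligand, receptor) gene pair names some but not all subunits of a
#' multi-subunit interaction, and the remaining subunits are not covered by
#' companion predictions for the same source/target — i.e. the complex is
#' only partially identified.
#'
#' @param predictions Data frame with columns `source`, `target`, `ligand`,
#'   `receptor` (single gene symbols).
#' @param db Ground-truth `lr_database`.
#' @return List: `fraction` (false positives / total predictions), `n_false`,
#'   `n_total`, `items` (predictions annotated with `false_positive` and the
#'   matched interaction).
#' @export
partial_complex_fpr <- function(predictions, db) {
  stopifnot(inherits(db, "lr_database"))
  preds <- as_tibble(predictions)
  required <- c("source", "target", "ligand", "receptor")
  stopifnot(all(required %in% names(preds)))
  n_total <- nrow(preds)
  fp <- logical(n_total)
  matched_id <- rep(NA_character_, n_total)
  for (p in seq_len(n_total)) {
    hits_partial <- FALSE
    hits_complete <- FALSE
    for (i in seq_len(nrow(db))) {
      lig <- db$ligand_subunits[[i]]
      rec <- db$receptor_subunits[[i]]
      if (!(preds$ligand[p] %in% lig && preds$receptor[p] %in% rec)) next
      if (is.na(matched_id[p])) matched_id[p] <- db$id[i]
      multi <- length(lig) > 1 || length(rec) > 1
      if (!multi) {
        hits_complete <- TRUE
        next
      }
      # companion predictions for the same source/target jointly covering
      # every subunit of the complex count as a complete identification
      same <- preds$source == preds$source[p] & preds$target == preds$target[p]
      covered_l <- all(lig %in% preds$ligand[same])
      covered_r <- all(rec %in% preds$receptor[same])
      if (covered_l && covered_r) hits_complete <- TRUE else hits_partial <- TRUE
    }
    fp[p] <- hits_partial && !hits_complete
  }
  items <- preds |>
    mutate(false_positive = fp, matched_interaction = matched_id)
  list(
    fraction = if (n_total > 0) sum(fp) / n_total else 0,
    n_false = sum(fp), n_total = n_total, items = items
  )
}

#' Robustness of inferred communications under cell subsampling
#'
#' For each subsampling fraction, draws a uniform random subsample of cells
#' stratified by group, re-runs the full inference, and compares the
#' significant (source, target, interaction) set against the full-data
#' result: TPR is the fraction of full-data significant entries recovered,
#' FPR the fraction of full-data non-significant entries called significant
#' in the subsample, and ACC the overall agreement over all K x K x N tested
#' entries.
#'
#' @param expr Genes x cells matrix.
#' @param grouping Cell grouping.
#' @param db An `lr_database`.
#' @param params A [comm_params()] (the inference seed inside is reused for
#'   both runs so an identity subsample reproduces the full result).
#' @param fractions Subsampling fractions (default 0.9, 0.8, 0.7).
#' @param seed Seed for the subsample draws.
#' @param full Optional precomputed full-data `comm_result`.
#' @return Tibble: `fraction`, `tpr`, `fpr`, `acc`, `n_significant_full`,
#'   `n_significant_sub`.
#' @export
subsample_robustness <- function(expr, grouping, db, params = comm_params(),
                                 fractions = c(0.9, 0.8, 0.7), seed = 1,
                                 full = NULL) {
  labels <- align_grouping(expr, grouping)
  full <- full %||% infer_communication(expr, labels, db, params)
  sig_set <- function(res) {
    td <- tidy(res)
    td$key <- paste(td$source, td$target, td$id, sep = "|")
    td$key[td$significant]
  }
  universe <- length(full$groups)^2 * nrow(full$pairs)
  full_sig <- sig_set(full)
  out <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    set.seed(seed + fi)
    keep <- unlist(lapply(levels(labels), function(grp) {
      idx <- which(labels == grp)
      if (f >= 1) idx else sample(idx, max(1, round(f * length(idx))))
    }))
    keep <- sort(keep)
    sub <- infer_communication(
      expr[, keep, drop = FALSE], droplevels(labels[keep]), db, params
    )
    sub_sig <- sig_set(sub)
    tp <- length(intersect(sub_sig, full_sig))
    fp_n <- length(setdiff(sub_sig, full_sig))
    negatives <- universe - length(full_sig)
    tn <- negatives - fp_n
    out[[fi]] <- tibble(
      fraction = f,
      tpr = if (length(full_sig) > 0) tp / length(full_sig) else NA_real_,
      fpr = if (negatives > 0) fp_n / negatives else NA_real_,
      acc = (tp + tn) / universe,
      n_significant_full = length(full_sig),
      n_significant_sub = length(sub_sig)
    )
  }
  bind_rows(out)
}
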