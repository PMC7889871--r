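#' Specification for synthetic communication data
#'
#' Bundles the parameters of the synthetic generator: a ligand-receptor
#' database with a controlled fraction of heteromeric complexes and
#' cofactor-bearing interactions, and a grouped expression matrix with
#' log-normal baseline noise, independent dropout, and planted directed
#' communication signals (elevated ligand expression in a source group and
#' receptor expression in a target group). Defaults emulate a small sorted
#' scRNA-seq experiment on the normalized [0, 1] expression scale the
#' mass-action model expects: 4 groups of 50 cells, 50 interactions over 5
#' pathways, 30% heteromeric receptors, 20% cofactor-bearing pairs, a
#' baseline trimean near 0.03, planted effects 10x baseline, and 20%
#' dropout.
#'
#' Baseline genes are detected only in a `baseline_detection` fraction of
#' cells (default 0.15), mirroring the sparsity of real scRNA-seq where
#' lowly expressed genes drop out in most cells; a group's trimean of such
#' a gene is exactly 0, which is the robustness the trimean summary is
#' chosen for. Planted genes are expressed throughout their planted group
#' (before the independent dropout). Setting `baseline_detection = 1`
#' yields a dense exchangeable matrix, the regime used to calibrate the
#' permutation test's type-I error, where a non-degenerate statistic is
#' required.
#'
#' @param n_groups Number of cell groups K.
#' @param cells_per_group Cells per group.
#' @param n_pairs Number of ligand-receptor interactions.
#' @param n_pathways Number of pathway families (>= 3).
#' @param heteromeric_fraction Fraction of interactions with a two-subunit
#'   receptor complex (realized exactly after rounding).
#' @param cofactor_fraction Fraction of interactions carrying agonist /
#'   antagonist / co-stimulatory / co-inhibitory gene sets.
#' @param n_planted Number of planted directed communications (distinct
#'   (pair, source, target) triples).
#' @param effect_size Fold elevation of planted ligand/receptor expression
#'   over baseline.
#' @param baseline_location Median of the log-normal baseline (default 0.03).
#' @param baseline_scale Log-scale sd of the baseline (default 0.5).
#' @param baseline_detection Fraction of cells in which a baseline gene is
#'   detected (default 0.15); 1 gives a dense matrix.
#' @param dropout Independent Bernoulli zeroing probability in [0, 1),
#'   applied on top of baseline sparsity. An expression-dependent option
#'   (`dropout_shape > 0`) zeroes low values preferentially.
#' @param dropout_shape Exponent tilting dropout toward low expression; 0
#'   (default) is constant-rate dropout.
#' @param seed Random seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_groups = 4, cells_per_group = 50, n_pairs = 50,
                           n_pathways = 5, heteromeric_fraction = 0.3,
                           cofactor_fraction = 0.2, n_planted = 10,
                           effect_size = 10, baseline_location = 0.03,
                           baseline_scale = 0.5, baseline_detection = 0.15,
                           dropout = 0.2, dropout_shape = 0, seed = 1L) {
  stopifnot(
    n_groups >= 2, cells_per_group >= 2, n_pairs >= 1, n_pathways >= 3,
    heteromeric_fraction >= 0, heteromeric_fraction <= 1,
    baseline_detection > 0, baseline_detection <= 1,
    dropout >= 0, dropout < 1, effect_size >= 0, dropout_shape >= 0
  )
  structure(
    list(
      n_groups = n_groups, cells_per_group = cells_per_group,
      n_pairs = n_pairs, n_pathways = n_pathways,
      heteromeric_fraction = heteromeric_fraction,
      cofactor_fraction = cofactor_fraction, n_planted = n_planted,
      effect_size = effect_size, baseline_location = baseline_location,
      baseline_scale = baseline_scale,
      baseline_detection = baseline_detection,
      dropout = dropout, dropout_shape = dropout_shape,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic ligand-receptor database
#'
#' Builds `n_pairs` interactions over `n_pathways` pathway families with a
#' distinct gene per role (ligands `Lg*`, receptor subunits `Rc*`, cofactors
#' `Ag*`/`An*`/`Cs*`/`Ci*`). The stated heteromeric and cofactor fractions
#' are realized exactly (after rounding): the first
#' `round(n_pairs * heteromeric_fraction)` interactions receive two-subunit
#' receptors, and cofactor sets rotate over the four classes.
#'
#' @param spec A [synthetic_spec()].
#' @return An `lr_database`.
#' @export
make_database <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pairs
  n_het <- round(n * spec$heteromeric_fraction)
  n_cof <- round(n * spec$cofactor_fraction)
  annotations <- c("secreted_signaling", "ecm_receptor", "cell_cell_contact")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lig <- sprintf("Lg%02d", i)
    rec <- if (i <= n_het) sprintf("Rc%02da,Rc%02db", i, i) else sprintf("Rc%02d", i)
    cof <- list(ag = "", an = "", cs = "", ci = "")
    if (i <= n_cof) {
      cls <- c("ag", "an", "cs", "ci")[(i - 1) %% 4 + 1]
      cof[[cls]] <- sprintf("%s%02d", c(ag = "Ag", an = "An", cs = "Cs", ci = "Ci")[cls], i)
    }
    rows[[i]] <- tibble(
      id = sprintf("INT%02d", i),
      ligand_subunits = lig,
      receptor_subunits = rec,
      agonists = cof$ag, antagonists = cof$an,
      co_stimulatory = cof$cs, co_inhibitory = cof$ci,
      pathway = sprintf("PW%d", (i - 1) %% spec$n_pathways + 1),
      annotation = annotations[(i - 1) %% 3 + 1],
      evidence = "synthetic"
    )
  }
  lr_database(bind_rows(rows))
}

#' Generate grouped expression with planted communication signals
#'
#' Baseline expression for every database gene is log-normal noise around
#' `baseline_location`, clipped to [0, 1]. For each planted directed edge
#' the ligand subunits are elevated (by `effect_size`-fold) in the source
#' group and the receptor subunits — plus any co-stimulatory genes of the
#' interaction — in the target group. Dropout then zeroes entries
#' independently. The planted ground truth is returned for scoring.
#'
#' @param spec A [synthetic_spec()].
#' @param db The database from [make_database()] (regenerated when omitted).
#' @param planted Optional tibble (`id`, `source`, `target`) selecting the
#'   planted edges; by default `n_planted` distinct triples are drawn.
#' @return List: `expression` (genes x cells dgCMatrix), `grouping`
#'   (`cell_grouping`), `truth` (tibble id/source/target/effect_size),
#'   `db`.
#' @export
make_expression <- function(spec, db = NULL, planted = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  db <- db %||% make_database(spec)
  set.seed(spec$seed)
  genes <- gene_universe(db)
  k <- spec$n_groups
  n_cells <- k * spec$cells_per_group
  groups <- paste0("G", seq_len(k))
  labels <- factor(rep(groups, each = spec$cells_per_group), levels = groups)
  cells <- sprintf("cell%04d", seq_len(n_cells))

  base_meanlog <- log(spec$baseline_location)
  x <- matrix(
    rlnorm(length(genes) * n_cells, base_meanlog, spec$baseline_scale),
    length(genes), n_cells, dimnames = list(genes, cells)
  )
  if (spec$baseline_detection < 1) {
    x[matrix(runif(length(x)) > spec$baseline_detection, nrow(x))] <- 0
  }

  if (is.null(planted)) {
    n_pl <- min(spec$n_planted, nrow(db))
    pair_ids <- sample(db$id, n_pl)
    planted <- tibble(
      id = pair_ids,
      source = sample(groups, n_pl, replace = TRUE),
      target = sample(groups, n_pl, replace = TRUE)
    )
  }
  planted$effect_size <- spec$effect_size
  high_meanlog <- log(pmin(spec$baseline_location * spec$effect_size, 0.8))
  for (e in seq_len(nrow(planted))) {
    row <- db[db$id == planted$id[e], ]
    lig <- row$ligand_subunits[[1]]
    rec <- c(row$receptor_subunits[[1]], row$co_stimulatory[[1]])
    src_cells <- labels == planted$source[e]
    tgt_cells <- labels == planted$target[e]
    x[lig, src_cells] <- rlnorm(length(lig) * sum(src_cells), high_meanlog, 0.25)
    x[rec, tgt_cells] <- rlnorm(length(rec) * sum(tgt_cells), high_meanlog, 0.25)
  }
  x[x > 1] <- 1
  if (spec$dropout > 0) {
    rate <- if (spec$dropout_shape > 0) {
      # expression-dependent dropout: low values are zeroed preferentially,
      # with marginal rate still equal to `dropout` at the baseline location
      spec$dropout * pmin(1, (spec$baseline_location / pmax(x, 1e-6)))^spec$dropout_shape
    } else {
      spec$dropout
    }
    x[matrix(runif(length(x)), nrow(x)) < rate] <- 0
  }
  list(
    expression = methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
    grouping = cell_grouping(cells, labels),
    truth = as_tibble(planted),
    db = db
  )
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the database (TSV), the expression matrix (Matrix Market triplet
#' plus gene/cell name lists), the group labels (TSV) and the planted truth
#' (TSV) into a directory. Fixed seeds reproduce byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data <- make_expression(spec)
  paths <- c(
    db = file.path(dir, "lr_database.tsv"),
    matrix = file.path(dir, "expression.mtx"),
    genes = file.path(dir, "genes.txt"),
    cells = file.path(dir, "cells.txt"),
    labels = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_lr_database(data$db, paths["db"])
  Matrix::writeMM(data$expression, paths["matrix"])
  writeLines(rownames(data$expression), paths["genes"])
  writeLines(colnames(data$expression), paths["cells"])
  readr::write_tsv(data$grouping, paths["labels"], progress = FALSE)
  readr::write_tsv(data$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
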