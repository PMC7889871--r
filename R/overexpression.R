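#' Identify over-expressed signaling genes per cell group
#'
#' For each gene of the database's gene universe present in the matrix and
#' each cell group, tests up-regulation of the group against all other cells
#' pooled with a one-sided Wilcoxon rank-sum test. No multiple-testing
#' correction is applied: the raw `alpha` threshold is a permissive
#' pre-filter ahead of the permutation significance test. Constant genes
#' short-circuit to p = 1 and are never flagged.
#'
#' @param expr Genes x cells expression matrix (sparse or dense).
#' @param grouping A `cell_grouping`, factor or label vector over cells.
#' @param db An `lr_database`; only its gene universe is tested. Pass `NULL`
#'   to test every gene in the matrix.
#' @param alpha Significance level for flagging (default 0.05).
#' @return Tibble: `gene`, `group`, `p_value`, `direction` (`"up"`/`"down"`
#'   by mean difference), `overexpressed` (p < alpha).
#' @export
identify_overexpressed <- function(expr, grouping, db = NULL, alpha = 0.05) {
  labels <- align_grouping(expr, grouping)
  if (nlevels(labels) < 2) abort("need at least 2 cell groups")
  if (any(table(labels) < 2)) abort("every group needs at least 2 cells")
  genes <- rownames(expr)
  if (!is.null(db)) {
    genes <- intersect(genes, gene_universe(db))
    if (length(genes) == 0) {
      abort("database/matrix gene overlap is empty")
    }
  }
  x <- as.matrix(expr[genes, , drop = FALSE])
  res <- vector("list", length(genes) * nlevels(labels))
  idx <- 1L
  for (g in seq_along(genes)) {
    v <- x[g, ]
    constant <- length(unique(v)) == 1
    for (grp in levels(labels)) {
      in_grp <- labels == grp
      if (constant) {
        p <- 1
        dir <- "up"
      } else {
        p <- suppressWarnings(
          wilcox.test(v[in_grp], v[!in_grp], alternative = "greater")$p.value
        )
        dir <- if (mean(v[in_grp]) >= mean(v[!in_grp])) "up" else "down"
      }
      res[[idx]] <- list(gene = genes[g], group = grp, p_value = p, direction = dir)
      idx <- idx + 1L
    }
  }
  out <- dplyr::bind_rows(res)
  out$group <- factor(out$group, levels = levels(labels))
  out$overexpressed <- out$p_value < alpha
  out
}

# interaction eligibility from a DE table: "any" = at least one ligand or
# receptor subunit flagged in some group; "all" = every subunit of the ligand
# complex, or every subunit of the receptor complex, flagged in some group
eligible_interactions <- function(db, de, strictness = c("any", "all")) {
  strictness <- match.arg(strictness)
  flagged <- unique(de$gene[de$overexpressed])
  map_lgl(seq_len(nrow(db)), function(i) {
    lig <- db$ligand_subunits[[i]]
    rec <- db$receptor_subunits[[i]]
    if (strictness == "any") {
      any(c(lig, rec) %in% flagged)
    } else {
      all(lig %in% flagged) || all(rec %in% flagged)
    }
  })
}
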