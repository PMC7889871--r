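#' Ligand-receptor interaction databases
#'
#' An `lr_database` is a tibble of ligand-receptor interaction rules, one row
#' per interaction. Ligands and receptors may be heteromeric complexes
#' (multiple required gene subunits, stored as list-columns), and each
#' interaction can carry four cofactor gene sets that modulate signaling:
#' soluble agonists and antagonists, and co-stimulatory / co-inhibitory
#' membrane-bound receptors. Interactions are grouped into pathway families
#' and annotated as secreted signaling, ECM-receptor, or cell-cell contact.
#'
#' @param interactions A data frame with columns `id`, `ligand_subunits`,
#'   `receptor_subunits`, `agonists`, `antagonists`, `co_stimulatory`,
#'   `co_inhibitory`, `pathway`, `annotation` and optionally `evidence`.
#'   Multi-gene fields may be comma-separated strings or list-columns of
#'   character vectors.
#' @return A validated `lr_database` tibble with gene fields as list-columns.
#' @examples
#' db <- lr_database(data.frame(
#'   id = "TGFB1_TGFBR", ligand_subunits = "Tgfb1",
#'   receptor_subunits = "Tgfbr1,Tgfbr2", agonists = "", antagonists = "",
#'   co_stimulatory = "", co_inhibitory = "",
#'   pathway = "TGFb", annotation = "secreted_signaling"
#' ))
#' gene_universe(db)
#' @export
lr_database <- function(interactions) {
  x <- as_tibble(interactions)
  required <- c(
    "id", "ligand_subunits", "receptor_subunits", "agonists", "antagonists",
    "co_stimulatory", "co_inhibitory", "pathway", "annotation"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "ligand-receptor table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "commscape_schema_error")
  }
  if (nrow(x) == 0) {
    abort("no interactions in ligand-receptor table",
      class = "commscape_validation_error"
    )
  }
  if (!"evidence" %in% names(x)) x$evidence <- ""
  gene_cols <- c(
    "ligand_subunits", "receptor_subunits", "agonists", "antagonists",
    "co_stimulatory", "co_inhibitory"
  )
  for (col in gene_cols) {
    if (!is.list(x[[col]])) x[[col]] <- split_genes(as.character(x[[col]]))
  }
  x$id <- as.character(x$id)
  x$pathway <- as.character(x$pathway)
  x$annotation <- as.character(x$annotation)
  validate_lr_database(x)
  x <- x[, c(required, "evidence")]
  class(x) <- c("lr_database", class(tibble()))
  x
}

validate_lr_database <- function(x) {
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate interaction id(s): ", paste(dup, collapse = ", ")),
      class = "commscape_validation_error"
    )
  }
  problems <- character(0)
  classes <- c("secreted_signaling", "ecm_receptor", "cell_cell_contact")
  for (i in seq_len(nrow(x))) {
    lig <- x$ligand_subunits[[i]]
    rec <- x$receptor_subunits[[i]]
    if (length(lig) < 1) {
      problems <- c(problems, sprintf("row %d (%s): empty ligand subunit list", i, x$id[i]))
    }
    if (length(rec) < 1) {
      problems <- c(problems, sprintf("row %d (%s): empty receptor subunit list", i, x$id[i]))
    }
    if (anyDuplicated(lig) || anyDuplicated(rec)) {
      problems <- c(problems, sprintf("row %d (%s): duplicated subunit genes", i, x$id[i]))
    }
    all_genes <- unlist(x[i, c(
      "ligand_subunits", "receptor_subunits", "agonists", "antagonists",
      "co_stimulatory", "co_inhibitory"
    )], use.names = FALSE)
    if (any(grepl("\\s", all_genes))) {
      problems <- c(problems, sprintf("row %d (%s): gene symbol contains whitespace", i, x$id[i]))
    }
    if (!nzchar(x$pathway[i]) || is.na(x$pathway[i])) {
      problems <- c(problems, sprintf("row %d (%s): empty pathway label", i, x$id[i]))
    }
    if (!x$annotation[i] %in% classes) {
      problems <- c(problems, sprintf(
        "row %d (%s): annotation '%s' is not one of %s",
        i, x$id[i], x$annotation[i], paste(classes, collapse = "/")
      ))
    }
  }
  if (length(problems) > 0) {
    abort(paste0(
      "invalid ligand-receptor interaction(s):\n",
      paste(problems, collapse = "\n")
    ), class = "commscape_validation_error")
  }
  invisible(x)
}

#' Read or write a ligand-receptor database
#'
#' The primary on-disk format is a flat UTF-8 TSV with one interaction per
#' row and comma-separated multi-gene fields; a JSON mirror keeps the nested
#' list structure. `read_lr_database(write_lr_database(db))` is an identity.
#'
#' @param path File path.
#' @param dialect `"tsv"` (flat table) or `"json"` (nested records).
#' @return An `lr_database`.
#' @export
read_lr_database <- function(path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("database file not found: ", path))
  }
  raw <- if (dialect == "tsv") {
    readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      na = character(), progress = FALSE
    )
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    as_tibble(recs$interactions %||% recs)
  }
  lr_database(raw)
}

#' @param db An `lr_database`.
#' @rdname read_lr_database
#' @export
write_lr_database <- function(db, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(db, "lr_database"))
  if (dialect == "tsv") {
    flat <- as_tibble(db)
    for (col in c(
      "ligand_subunits", "receptor_subunits", "agonists", "antagonists",
      "co_stimulatory", "co_inhibitory"
    )) {
      flat[[col]] <- join_genes(flat[[col]])
    }
    readr::write_tsv(flat, path, progress = FALSE)
  } else {
    jsonlite::write_json(list(interactions = as_tibble(db)), path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' All gene symbols referenced by a database
#'
#' @param db An `lr_database`.
#' @return Character vector of unique gene symbols (subunits and cofactors).
#' @export
gene_universe <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  unique(unlist(db[, c(
    "ligand_subunits", "receptor_subunits", "agonists", "antagonists",
    "co_stimulatory", "co_inhibitory"
  )], use.names = FALSE))
}

#' Subset a database by annotation class and/or pathway
#'
#' @param db An `lr_database`.
#' @param annotation Optional annotation class to keep.
#' @param pathways Optional character vector of pathway labels to keep; labels
#'   absent from the database are an error.
#' @return The filtered `lr_database`.
#' @export
subset_lr_database <- function(db, annotation = NULL, pathways = NULL) {
  stopifnot(inherits(db, "lr_database"))
  keep <- rep(TRUE, nrow(db))
  if (!is.null(annotation)) {
    keep <- keep & db$annotation %in% annotation
  }
  if (!is.null(pathways)) {
    unknown <- setdiff(pathways, db$pathway)
    if (length(unknown) > 0) {
      abort(paste0(
        "pathway label(s) not in database: ",
        paste(unknown, collapse = ", ")
      ))
    }
    keep <- keep & db$pathway %in% pathways
  }
  lr_database(as_tibble(db)[keep, , drop = FALSE])
}

#' Summary statistics of a ligand-receptor database
#'
#' Counts interactions and pathways and reports the fraction of interactions
#' in each annotation class and the fraction with a heteromeric (multi-
#' subunit) ligand or receptor.
#'
#' @param db An `lr_database`.
#' @return One-row tibble: `n_interactions`, `n_pathways`,
#'   `frac_secreted_signaling`, `frac_ecm_receptor`, `frac_cell_cell_contact`,
#'   `frac_heteromeric`, `n_genes`.
#' @export
lr_database_stats <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  hetero <- map_lgl(seq_len(nrow(db)), function(i) {
    length(db$ligand_subunits[[i]]) > 1 || length(db$receptor_subunits[[i]]) > 1
  })
  tibble(
    n_interactions = nrow(db),
    n_pathways = length(unique(db$pathway)),
    frac_secreted_signaling = mean(db$annotation == "secreted_signaling"),
    frac_ecm_receptor = mean(db$annotation == "ecm_receptor"),
    frac_cell_cell_contact = mean(db$annotation == "cell_cell_contact"),
    frac_heteromeric = mean(hetero),
    n_genes = length(gene_universe(db))
  )
}

#' @method glance lr_database
#' @export
glance.lr_database <- function(x, ...) lr_database_stats(x)

#' Display name of a complex: subunits joined by underscores
#'
#' @param subunits Character vector of subunit gene symbols.
#' @return A single string, e.g. `"Tgfbr1_Tgfbr2"`.
#' @export
complex_name <- function(subunits) paste(subunits, collapse = "_")

#' @method print lr_database
#' @export
print.lr_database <- function(x, ...) {
  s <- lr_database_stats(x)
  cat(sprintf(
    "<lr_database> %d interactions, %d pathways, %.0f%% heteromeric\n",
    s$n_interactions, s$n_pathways, 100 * s$frac_heteromeric
  ))
  NextMethod()
}
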