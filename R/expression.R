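#' Read a genes-by-cells expression matrix
#'
#' Accepts either a Matrix Market sparse triplet file plus gene and cell name
#' lists (one name per line), or a dense TSV with gene identifiers in the
#' first column and one column per cell. Values are assumed library-normalized
#' and log-transformed upstream; they must be non-negative. The mass-action
#' model expects expression roughly in the [0, 1] range (half-saturation
#' `kh = 0.5`); [infer_communication()] warns when the matrix maximum exceeds
#' a configurable bound.
#'
#' @param matrix_path Path to the `.mtx` triplet file or the dense TSV.
#' @param genes_path,cells_path Paths to newline-delimited name lists
#'   (Matrix Market dialect only).
#' @param dialect `"matrix_market"` or `"tsv"`.
#' @return A `dgCMatrix` (genes x cells) with gene/cell dimnames.
#' @export
read_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                            dialect = c("matrix_market", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(matrix_path)) {
    abort(paste0("expression file not found: ", matrix_path))
  }
  if (dialect == "matrix_market") {
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      abort(sprintf(
        "dimension mismatch: matrix is %d x %d but %d gene names and %d cell names were given",
        nrow(m), ncol(m), length(genes), length(cells)
      ))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- readr::read_tsv(matrix_path,
      col_types = readr::cols(
        readr::col_character(),
        .default = readr::col_double()
      ), progress = FALSE
    )
    genes <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- genes
    m <- methods::as(Matrix::Matrix(vals, sparse = TRUE), "CsparseMatrix")
  }
  validate_expression(m)
  m
}

validate_expression <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("expression matrix must have gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(m))) {
    abort("duplicated gene names in expression matrix")
  }
  neg <- which(m@x < 0)
  if (length(neg) > 0) {
    trip <- Matrix::summary(m)
    bad <- trip[trip$x < 0, , drop = FALSE][1, ]
    abort(sprintf(
      "negative expression value %.4g at gene %s, cell %s",
      bad$x, rownames(m)[bad$i], colnames(m)[bad$j]
    ))
  }
  invisible(m)
}

#' Construct a cell grouping
#'
#' @param cells Character vector of cell names, or a two-column data frame
#'   `(cell, group)`.
#' @param labels Group label per cell (ignored when `cells` is a data frame).
#' @return A `cell_grouping` tibble with columns `cell` and `group` (factor).
#' @export
cell_grouping <- function(cells, labels = NULL) {
  if (is.data.frame(cells)) {
    df <- as_tibble(cells)
    names(df)[1:2] <- c("cell", "group")
  } else {
    stopifnot(length(cells) == length(labels))
    df <- tibble(cell = as.character(cells), group = labels)
  }
  df$cell <- as.character(df$cell)
  if (!is.factor(df$group)) df$group <- factor(df$group)
  df$group <- droplevels(df$group)
  if (anyDuplicated(df$cell)) abort("duplicated cell names in grouping")
  class(df) <- c("cell_grouping", class(tibble()))
  df
}

#' Read a two-column (cell, group) TSV
#' @param path File path; header required.
#' @return A `cell_grouping`.
#' @export
read_cell_grouping <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  cell_grouping(df)
}

# align a grouping to the columns of an expression matrix, returning a factor
# in matrix column order
align_grouping <- function(expr, grouping) {
  if (inherits(grouping, "cell_grouping") || is.data.frame(grouping)) {
    grouping <- cell_grouping(grouping)
    idx <- match(colnames(expr), grouping$cell)
    if (anyNA(idx)) {
      abort(paste0(
        "cells missing from grouping: ",
        paste(head(colnames(expr)[is.na(idx)], 5), collapse = ", ")
      ))
    }
    labels <- grouping$group[idx]
  } else {
    if (length(grouping) != ncol(expr)) {
      abort("grouping length does not match number of cells")
    }
    labels <- if (is.factor(grouping)) grouping else factor(grouping)
  }
  droplevels(labels)
}

#' Group sizes of a grouping
#' @param grouping A `cell_grouping`, factor or label vector.
#' @return Tibble with columns `group`, `n_cells`.
#' @export
group_sizes <- function(grouping) {
  labels <- if (is.data.frame(grouping)) cell_grouping(grouping)$group else factor(grouping)
  tibble(group = levels(labels), n_cells = as.integer(table(labels)))
}
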