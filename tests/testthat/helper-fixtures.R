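# small in-code fixtures shared across tests

tiny_db <- function() {
  lr_database(tibble::tibble(
    id = c("TGFB1_R12", "WNT1_FZD1", "IL2_IL2R"),
    ligand_subunits = c("Tgfb1", "Wnt1", "Il2"),
    receptor_subunits = c("Tgfbr1,Tgfbr2", "Fzd1", "Il2ra,Il2rb,Il2rg"),
    agonists = c("", "Rspo1", ""),
    antagonists = c("Dcn", "", ""),
    co_stimulatory = c("", "", "Cd28"),
    co_inhibitory = c("Ctla4", "", ""),
    pathway = c("TGFb", "WNT", "IL"),
    annotation = c("secreted_signaling", "secreted_signaling", "cell_cell_contact"),
    evidence = "fixture"
  ))
}

# dense expression matrix with named genes/cells
dense_expr <- function(values, genes, cells) {
  m <- matrix(values, length(genes), length(cells),
    dimnames = list(genes, cells)
  )
  Matrix::Matrix(m, sparse = TRUE)
}

# two-group toy dataset: `gene_hi` at `hi` in group A, everything else `lo`
toy_two_groups <- function(n_per_group = 50, genes = c("Tgfb1", "Tgfbr1", "Tgfbr2"),
                           gene_hi = "Tgfb1", hi = 5, lo = 0) {
  n <- 2 * n_per_group
  cells <- sprintf("c%03d", seq_len(n))
  x <- matrix(lo, length(genes), n, dimnames = list(genes, cells))
  labels <- factor(rep(c("A", "B"), each = n_per_group))
  x[gene_hi, labels == "A"] <- hi
  list(
    expr = Matrix::Matrix(x, sparse = TRUE),
    grouping = cell_grouping(cells, labels)
  )
}

# wrap an adjacency matrix as a network
net_from_adj <- function(adj, pathway = "P") {
  comm_network(pathway, adj)
}

named_adj <- function(k, values = 0) {
  grp <- LETTERS[seq_len(k)]
  matrix(values, k, k, dimnames = list(grp, grp))
}
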