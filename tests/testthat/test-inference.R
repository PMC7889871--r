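# constant-within-group dataset: trimeans equal the set values exactly,
# so Eq-level arithmetic can be checked against the scalar oracle
constant_dataset <- function(values_by_group, n_per_group = 12) {
  genes <- rownames(values_by_group)
  groups <- colnames(values_by_group)
  n <- n_per_group * length(groups)
  cells <- sprintf("c%03d", seq_len(n))
  labels <- factor(rep(groups, each = n_per_group), levels = groups)
  x <- matrix(0, length(genes), n, dimnames = list(genes, cells))
  for (g in groups) x[, labels == g] <- values_by_group[, g]
  list(
    expr = Matrix::Matrix(x, sparse = TRUE),
    grouping = cell_grouping(cells, labels)
  )
}

one_pair_db <- function(agonists = "", antagonists = "", co_stimulatory = "",
                        co_inhibitory = "", receptor = "R1") {
  lr_database(tibble::tibble(
    id = "P1", ligand_subunits = "L1", receptor_subunits = receptor,
    agonists = agonists, antagonists = antagonists,
    co_stimulatory = co_stimulatory, co_inhibitory = co_inhibitory,
    pathway = "PW", annotation = "secreted_signaling"
  ))
}

quiet_params <- function(...) comm_params(min_cells = 2, permutations = 2, ...)

test_that("trimean matches the type-7 quantile oracle", {
  expect_equal(trimean(c(1, 2, 3, 4, 5)), 3.0)
  expect_equal(trimean(rep(2.5, 9)), 2.5)
  # > 75% zeros: Q1 = Q2 = Q3 = 0, so the trimean collapses to 0
  expect_equal(trimean(c(0, 0, 0, 0, 0, 0, 0, 1)), oracle_trimean(c(rep(0, 7), 1)))
  expect_equal(trimean(c(0, 0, 0, 0, 0, 0, 0, 1)), 0)
  set.seed(21)
  for (len in c(2:8, 37)) {
    v <- rlnorm(len)
    expect_equal(trimean(v), oracle_trimean(v))
  }
  expect_error(trimean(numeric(0)), "empty")
})

test_that("row trimeans agree with the scalar version", {
  set.seed(8)
  x <- matrix(rlnorm(300), 20)
  expect_equal(
    unname(commscape:::row_trimean(x)),
    apply(x, 1, trimean)
  )
})

test_that("group expression is the per-group trimean and is order-invariant", {
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 0, 0, 0, 0, 0))
  cells <- sprintf("c%02d", 1:10)
  expr <- dense_expr(vals, "g1", cells)
  labels <- factor(rep(c("A", "B"), each = 5))
  ge <- group_expression(expr, cell_grouping(cells, labels))
  expect_equal(ge$expression[ge$group == "A"], 3.0)
  expect_equal(ge$expression[ge$group == "B"], 0.0)
  perm <- c(7, 2, 9, 1, 5, 3, 10, 4, 6, 8)
  ge2 <- group_expression(
    expr[, perm, drop = FALSE],
    cell_grouping(cells[perm], labels[perm])
  )
  expect_equal(ge2, ge)
})

test_that("complex expression is a zero-annihilating geometric mean", {
  expect_equal(complex_expression(c(a = 4, b = 1), c("a", "b")), 2)
  expect_equal(complex_expression(c(a = 7, b = 0), c("a", "b")), 0)
  expect_equal(complex_expression(c(a = 3.7), "a"), 3.7)
  # missing subunit inactivates the complex
  expect_equal(complex_expression(c(a = 5), c("a", "zz")), 0)
})

test_that("receptor modulation is linear in the cofactor means", {
  expect_equal(modulated_receptor(1, 1, 0), 2)
  expect_equal(modulated_receptor(1, 0, 1), 0.5)
  expect_equal(modulated_receptor(3.2, 0, 0), 3.2)
})

test_that("mass-action probabilities reproduce hand-computed values", {
  vals <- rbind(L1 = c(1, 0), R1 = c(0, 1))
  colnames(vals) <- c("A", "B")
  ds <- constant_dataset(vals)
  # population factor off: P(A->B) = (1*1)/(0.5 + 1) = 2/3
  res <- infer_communication(
    ds$expr, ds$grouping, one_pair_db(),
    quiet_params(population_size = FALSE), de = NA
  )
  expect_equal(res$prob["A", "B", "P1"], 2 / 3)
  expect_equal(res$prob["B", "A", "P1"], 0) # ligand absent in B
  # equal group sizes: population factor multiplies by 1/4
  res_pop <- infer_communication(
    ds$expr, ds$grouping, one_pair_db(), quiet_params(), de = NA
  )
  expect_equal(res_pop$prob["A", "B", "P1"], (2 / 3) * (1 / 4))
})

test_that("antagonists at the half-saturation level quarter the score", {
  vals <- rbind(L1 = c(1, 0), R1 = c(0, 1), AN1 = c(0.5, 0.5))
  colnames(vals) <- c("A", "B")
  ds <- constant_dataset(vals)
  res <- infer_communication(
    ds$expr, ds$grouping, one_pair_db(antagonists = "AN1"),
    quiet_params(population_size = FALSE), de = NA
  )
  expect_equal(res$prob["A", "B", "P1"], (2 / 3) * 0.25)
})

test_that("cofactor and complex arithmetic matches the scalar oracle", {
  set.seed(77)
  for (rep_i in 1:10) {
    l <- runif(1, 0, 1)
    r1 <- runif(1, 0, 1)
    r2 <- runif(1, 0, 1)
    ag <- runif(1, 0, 1)
    an <- runif(1, 0, 1)
    cs <- runif(1, 0, 1)
    vals <- rbind(
      L1 = c(l, 0), R1a = c(0, r1), R1b = c(0, r2),
      AG1 = c(ag, ag), AN1 = c(an, an), CS1 = c(0, cs)
    )
    colnames(vals) <- c("A", "B")
    ds <- constant_dataset(vals)
    db <- lr_database(tibble::tibble(
      id = "P1", ligand_subunits = "L1", receptor_subunits = "R1a,R1b",
      agonists = "AG1", antagonists = "AN1", co_stimulatory = "CS1",
      co_inhibitory = "", pathway = "PW", annotation = "secreted_signaling"
    ))
    res <- infer_communication(
      ds$expr, ds$grouping, db,
      quiet_params(population_size = FALSE), de = NA
    )
    expected <- oracle_probability(
      lig = l, rec = c(r1, r2), ag_i = ag, ag_j = ag, an_i = an, an_j = an,
      ra = cs
    )
    expect_equal(res$prob["A", "B", "P1"], expected, tolerance = 1e-12)
  }
})

test_that("a zero-expressed receptor subunit silences the pair everywhere", {
  vals <- rbind(L1 = c(1, 1), R1a = c(1, 1), R1b = c(0, 0))
  colnames(vals) <- c("A", "B")
  ds <- constant_dataset(vals)
  res <- infer_communication(
    ds$expr, ds$grouping, one_pair_db(receptor = "R1a,R1b"),
    quiet_params(), de = NA
  )
  expect_true(all(res$prob == 0))
})

test_that("the score is monotone in ligand, receptor and cofactors", {
  set.seed(13)
  prob_at <- function(l, r, ag, an) {
    vals <- rbind(
      L1 = c(l, 0), R1 = c(0, r), AG1 = c(ag, 0), AN1 = c(an, 0)
    )
    colnames(vals) <- c("A", "B")
    ds <- constant_dataset(vals, n_per_group = 4)
    db <- one_pair_db(agonists = "AG1", antagonists = "AN1")
    infer_communication(
      ds$expr, ds$grouping, db,
      quiet_params(population_size = FALSE), de = NA
    )$prob["A", "B", "P1"]
  }
  for (rep_i in 1:5) {
    base <- runif(4, 0.1, 0.9)
    delta <- runif(1, 0.05, 0.5)
    p0 <- prob_at(base[1], base[2], base[3], base[4])
    expect_gte(prob_at(base[1] + delta, base[2], base[3], base[4]), p0)
    expect_gte(prob_at(base[1], base[2] + delta, base[3], base[4]), p0)
    expect_gte(prob_at(base[1], base[2], base[3] + delta, base[4]), p0)
    expect_lte(prob_at(base[1], base[2], base[3], base[4] + delta), p0)
  }
})

test_that("the Hill curve saturates at 1 and is half-maximal at kh", {
  prob_at_lr <- function(l) {
    vals <- rbind(L1 = c(l, 0), R1 = c(0, 1))
    colnames(vals) <- c("A", "B")
    ds <- constant_dataset(vals, n_per_group = 4)
    infer_communication(
      ds$expr, ds$grouping, one_pair_db(),
      quiet_params(population_size = FALSE, max_expression = 1e9), de = NA
    )$prob["A", "B", "P1"]
  }
  expect_equal(prob_at_lr(0.5), 0.5) # L*R = kh
  expect_gt(prob_at_lr(5e4), 0.99999)
})

test_that("toggling the population factor rescales every entry exactly", {
  spec <- synthetic_spec(n_groups = 3, cells_per_group = c(30), n_pairs = 10, seed = 3)
  data <- make_expression(spec)
  p_on <- infer_communication(
    data$expression, data$grouping, data$db,
    comm_params(permutations = 2, seed = 1), de = NA
  )
  p_off <- infer_communication(
    data$expression, data$grouping, data$db,
    comm_params(permutations = 2, population_size = FALSE, seed = 1), de = NA
  )
  sizes <- p_on$group_sizes
  n <- sum(sizes)
  for (i in seq_along(sizes)) {
    for (j in seq_along(sizes)) {
      expect_equal(
        p_off$prob[i, j, ] * sizes[i] * sizes[j] / n^2,
        p_on$prob[i, j, ],
        tolerance = 1e-12
      )
    }
  }
})

test_that("exchangeable cells give p = 1 everywhere", {
  vals <- rbind(L1 = c(0.6, 0.6), R1 = c(0.6, 0.6))
  colnames(vals) <- c("A", "B")
  ds <- constant_dataset(vals)
  res <- infer_communication(
    ds$expr, ds$grouping, one_pair_db(),
    comm_params(min_cells = 2, permutations = 25, seed = 4), de = NA
  )
  expect_true(all(res$pval == 1))
})

test_that("a planted sender-receiver pair is significant only where planted", {
  set.seed(19)
  n <- 200
  cells <- sprintf("c%03d", 1:n)
  labels <- factor(rep(c("A", "B", "C", "D"), each = 50))
  x <- matrix(0, 2, n, dimnames = list(c("L1", "R1"), cells))
  x["L1", labels == "A"] <- rlnorm(50, log(5), 0.1)
  x["R1", labels == "B"] <- rlnorm(50, log(5), 0.1)
  res <- infer_communication(
    Matrix::Matrix(x, sparse = TRUE), cell_grouping(cells, labels),
    one_pair_db(),
    comm_params(permutations = 100, seed = 6, max_expression = 20), de = NA
  )
  expect_lte(res$pval["A", "B", "P1"], 0.01)
  other <- res$pval[, , "P1"]
  other["A", "B"] <- NA
  expect_true(all(other[!is.na(other)] == 1))
})

test_that("inference is reproducible and invariant to input ordering", {
  spec <- synthetic_spec(n_pairs = 8, n_planted = 3, seed = 12)
  data <- make_expression(spec)
  params <- comm_params(permutations = 20, seed = 5)
  r1 <- infer_communication(data$expression, data$grouping, data$db, params)
  r2 <- infer_communication(data$expression, data$grouping, data$db, params)
  expect_identical(r1$prob, r2$prob)
  expect_identical(r1$pval, r2$pval)
  # permute genes: identical arrays
  gperm <- sample(nrow(data$expression))
  r3 <- infer_communication(
    data$expression[gperm, ], data$grouping, data$db, params
  )
  expect_equal(r3$prob, r1$prob)
})

test_that("tidy and glance summarize the tensor consistently", {
  spec <- synthetic_spec(n_pairs = 6, n_planted = 2, seed = 2)
  data <- make_expression(spec)
  res <- infer_communication(
    data$expression, data$grouping, data$db,
    comm_params(permutations = 10, seed = 1)
  )
  td <- tidy(res)
  expect_equal(nrow(td), 4 * 4 * 6)
  expect_equal(sum(td$prob), sum(res$prob))
  g <- glance(res)
  expect_equal(g$n_significant_entries, sum(td$significant))
})
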