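# a planted block role matrix: `blocks` groups-per-block x signals-per-block
planted_role_matrix <- function(n_blocks = 3, groups_per = 4, signals_per = 5,
                                noise = 0.05, seed = 1) {
  set.seed(seed)
  k <- n_blocks * groups_per
  n <- n_blocks * signals_per
  pj <- matrix(runif(k * n, 0, noise), k, n)
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1) * groups_per + 1):(b * groups_per)
    cols <- ((b - 1) * signals_per + 1):(b * signals_per)
    # rank-one block: group intensity x signal intensity
    pj[rows, cols] <- pj[rows, cols] +
      outer(runif(groups_per, 0.8, 1), runif(signals_per, 0.8, 1))
  }
  dimnames(pj) <- list(paste0("G", 1:k), paste0("S", 1:n))
  pj
}

test_that("role matrices collapse the tensor with conserved totals", {
  groups <- c("A", "B")
  prob <- array(0, c(2, 2, 2), dimnames = list(groups, groups, c("p1", "p2")))
  pval <- array(1, dim(prob), dimnames = dimnames(prob))
  prob["A", "B", "p1"] <- 0.4
  pval["A", "B", "p1"] <- 0
  res <- structure(
    list(
      prob = prob, pval = pval,
      pairs = tibble::tibble(id = c("p1", "p2"), pathway = c("X", "Y"), eligible = TRUE),
      groups = groups, group_sizes = c(A = 10L, B = 10L),
      params = comm_params()
    ),
    class = "comm_result"
  )
  outgoing <- build_role_matrix(res, "outgoing")
  incoming <- build_role_matrix(res, "incoming")
  expect_equal(outgoing["A", "X"], 0.4)
  expect_equal(incoming["B", "X"], 0.4)
  expect_equal(sum(outgoing), sum(incoming))
  expect_equal(sum(outgoing), 0.4)
  # empty tensor -> zero matrix
  res$pval[] <- 1
  expect_equal(sum(build_role_matrix(res, "outgoing")), 0)
})

test_that("an exact rank-one matrix is reconstructed nearly perfectly", {
  set.seed(4)
  w <- matrix(runif(6, 0.5, 1), 6, 1)
  h <- matrix(runif(8, 0.5, 1), 1, 8)
  v <- w %*% h
  dec <- nmf_factorize(v, r = 1, n_runs = 3, seed = 2)
  rel_err <- dec$error / sqrt(sum(v^2))
  expect_lt(rel_err, 1e-6)
  expect_true(all(dec$w >= 0) && all(dec$h >= 0))
})

test_that("reconstruction error is non-increasing in the pattern count", {
  pj <- planted_role_matrix(seed = 6)
  errs <- vapply(2:5, function(r) {
    nmf_factorize(pj, r, n_runs = 4, seed = 3)$error
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("infeasible pattern counts error out", {
  pj <- planted_role_matrix(n_blocks = 2, groups_per = 2, signals_per = 2)
  expect_error(nmf_factorize(pj, r = 4), "must be below")
})

test_that("three planted blocks select three patterns with clean diagnostics", {
  hits <- 0
  for (s in 1:10) {
    pj <- planted_role_matrix(n_blocks = 3, noise = 0.05, seed = 100 + s)
    sel <- select_pattern_number(pj, candidate_r = 2:6, n_runs = 8, seed = s)
    if (sel$r == 3) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("a noiseless block matrix reaches cophenetic one at the true count", {
  pj <- planted_role_matrix(n_blocks = 3, noise = 0, seed = 5)
  sel <- select_pattern_number(pj, candidate_r = 2:5, n_runs = 6, seed = 9)
  diag3 <- sel$diagnostics[sel$diagnostics$r == 3, ]
  expect_equal(diag3$cophenetic, 1, tolerance = 1e-9)
  expect_equal(nrow(sel$diagnostics), 4) # one row per candidate
})

test_that("planted group-to-pattern assignment is recovered at low noise", {
  pj <- planted_role_matrix(n_blocks = 3, noise = 0.05, seed = 42)
  truth <- rep(1:3, each = 4)
  dec <- nmf_factorize(pj, r = 3, n_runs = 10, seed = 8)
  assign <- apply(dec$w, 1, which.max)
  tab <- table(assign, truth)
  expect_gte(sum(apply(tab, 2, max)) / length(truth), 0.9)
})

test_that("loading thresholds implement the alluvial and dotplot rules", {
  dec <- structure(
    list(
      w = matrix(c(0.2, 1.0, 0.6, 0.3), 2, 2,
        dimnames = list(c("A", "B"), c("pattern1", "pattern2"))
      ),
      h = matrix(c(1, 0.1, 0.4, 0.9), 2, 2,
        dimnames = list(c("pattern1", "pattern2"), c("X", "Y"))
      ),
      r = 2, error = 0, direction = "outgoing"
    ),
    class = "pattern_decomposition"
  )
  allu <- threshold_loadings(dec, "alluvial")
  # row A of W normalizes to (0, 1): the small entry is zeroed
  expect_equal(unname(allu$w["A", ]), c(0, 1))
  dot <- threshold_loadings(dec, "dotplot") # cutoff 1/2
  expect_true(all(dot$w %in% c(0, dot$w[dot$w >= 0.5])))
  # all-equal row maps to all ones and survives
  dec$w["A", ] <- c(0.3, 0.3)
  allu2 <- threshold_loadings(dec, "alluvial")
  expect_equal(unname(allu2$w["A", ]), c(1, 1))
})

test_that("contribution scores are the W H product", {
  w <- matrix(c(1, 0), 2, 1)
  h <- matrix(c(0.5, 0.5), 1, 2)
  dec <- structure(
    list(w = w, h = h, r = 1, error = 0, direction = "outgoing"),
    class = "pattern_decomposition"
  )
  sc <- contribution_scores(dec)
  expect_equal(sc[1, ], c(0.5, 0.5))
  expect_equal(sc[2, ], c(0, 0))
  expect_true(all(sc >= 0))
  # near-exact factorization reproduces the input
  pj <- planted_role_matrix(n_blocks = 2, noise = 0, seed = 3)
  dec2 <- nmf_factorize(pj, r = 2, n_runs = 6, seed = 4)
  expect_lt(max(abs(contribution_scores(dec2) - pj)), 0.05)
})
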