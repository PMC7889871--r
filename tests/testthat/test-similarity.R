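test_that("functional similarity is the edge-set Jaccard index", {
  a <- named_adj(3)
  a["A", "B"] <- 0.5
  a["B", "C"] <- 0.1
  b <- named_adj(3)
  b["B", "C"] <- 0.7
  b["C", "A"] <- 0.2
  expect_equal(functional_similarity(net_from_adj(a), net_from_adj(b)), 1 / 3)
  expect_equal(functional_similarity(net_from_adj(a), net_from_adj(a)), 1)
  disjoint <- named_adj(3)
  disjoint["C", "B"] <- 1
  expect_equal(functional_similarity(net_from_adj(a), net_from_adj(disjoint)), 0)
  # both empty -> 1 by convention; mismatched groups -> error
  expect_equal(
    functional_similarity(net_from_adj(named_adj(3)), net_from_adj(named_adj(3))), 1
  )
  bad <- named_adj(4)
  expect_error(
    functional_similarity(net_from_adj(a), net_from_adj(bad)),
    "same cell group"
  )
  # the literal printed form divides by the symmetric difference
  expect_equal(
    functional_similarity(net_from_adj(a), net_from_adj(b), printed_form = TRUE),
    1 / 2
  )
})

test_that("structural dissimilarity vanishes on identical graphs", {
  set.seed(2)
  for (rep_i in 1:5) {
    adj <- named_adj(5, rbinom(25, 1, 0.4) * runif(25))
    diag(adj) <- 0
    net <- net_from_adj(adj)
    expect_equal(structural_dissimilarity(net, net), 0)
  }
})

test_that("complete graphs have zero node dispersion", {
  full <- named_adj(4, 1)
  diag(full) <- 0
  chain <- named_adj(4)
  chain["A", "B"] <- chain["B", "C"] <- chain["C", "D"] <- 1
  d_full_chain <- structural_dissimilarity(net_from_adj(full), net_from_adj(chain))
  # the NND term of the complete graph is exactly zero, so the w2 term is
  # the chain's dispersion alone
  dd_chain <- commscape:::distance_distributions(1 * (chain + t(chain) > 0))
  expect_gt(commscape:::nnd_value(dd_chain), 0)
  expect_gt(d_full_chain, 0)
})

test_that("star and path dissimilarity matches the brute-force oracle", {
  star <- named_adj(4)
  star["A", c("B", "C", "D")] <- 1
  path <- named_adj(4)
  path["A", "B"] <- path["B", "C"] <- path["C", "D"] <- 1
  impl <- structural_dissimilarity(net_from_adj(star), net_from_adj(path))
  orac <- oracle_structural_d(
    1 * ((star + t(star)) > 0), 1 * ((path + t(path)) > 0)
  )
  expect_equal(impl, orac, tolerance = 1e-9)
  expect_gt(impl, 0)
})

test_that("dissimilarity matches the oracle on all small graphs", {
  graphs4 <- all_graphs(4)
  for (i in seq_along(graphs4)) {
    for (j in seq_len(i)) {
      impl <- structural_dissimilarity(
        net_from_adj(graphs4[[i]]), net_from_adj(graphs4[[j]])
      )
      orac <- oracle_structural_d(graphs4[[i]], graphs4[[j]])
      expect_equal(impl, orac, tolerance = 1e-8)
      expect_gte(impl, 0)
      expect_lte(impl, 1)
    }
  }
})

test_that("dissimilarity is symmetric and bounded on random graph pairs", {
  set.seed(33)
  for (rep_i in 1:10) {
    a <- matrix(rbinom(36, 1, 0.35), 6, 6)
    b <- matrix(rbinom(36, 1, 0.35), 6, 6)
    a <- 1 * ((a + t(a)) > 0)
    b <- 1 * ((b + t(b)) > 0)
    diag(a) <- diag(b) <- 0
    dimnames(a) <- dimnames(b) <- list(LETTERS[1:6], LETTERS[1:6])
    d_ab <- structural_dissimilarity(net_from_adj(a), net_from_adj(b))
    d_ba <- structural_dissimilarity(net_from_adj(b), net_from_adj(a))
    expect_equal(d_ab, d_ba, tolerance = 1e-12)
    expect_gte(d_ab, 0)
    expect_lte(d_ab, 1)
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(7)
  nets <- lapply(1:4, function(i) {
    adj <- named_adj(4, rbinom(16, 1, 0.4) * runif(16))
    diag(adj) <- 0
    net_from_adj(adj, pathway = paste0("PW", i))
  })
  names(nets) <- paste0("PW", 1:4)
  for (kind in c("functional", "structural")) {
    s <- similarity_matrix(nets, kind = kind)
    expect_equal(unclass(s), t(unclass(s)))
    expect_equal(unname(diag(s)), rep(1, 4))
    expect_true(all(s >= 0 & s <= 1 + 1e-12))
  }
})
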