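# block-structured similarity over n pathways (two planted families)
block_similarity <- function(n = 12, within = 0.9, between = 0.05, noise = 0.02,
                             seed = 1) {
  set.seed(seed)
  half <- n / 2
  s <- matrix(between, n, n) + matrix(runif(n * n, 0, noise), n, n)
  s[1:half, 1:half] <- within
  s[(half + 1):n, (half + 1):n] <- within
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("PW", 1:n), paste0("PW", 1:n))
  s
}

test_that("the SNN neighborhood size is the square root of the pathway count", {
  s <- block_similarity(n = 9)
  sm <- snn_smooth(s)
  expect_equal(attr(sm, "snn_k"), 3)
  expect_equal(dim(sm), c(9L, 9L))
  expect_equal(sm, t(sm))
})

test_that("smoothing preserves planted block structure", {
  s <- block_similarity(n = 12, seed = 3)
  sm <- snn_smooth(s)
  within <- c(sm[1:6, 1:6][upper.tri(sm[1:6, 1:6])], sm[7:12, 7:12][upper.tri(sm[7:12, 7:12])])
  across <- as.vector(sm[1:6, 7:12])
  expect_gt(min(within), max(across))
})

test_that("planted similarity blocks separate on the manifold", {
  ok <- 0
  for (s_i in 1:10) {
    s <- block_similarity(n = 12, seed = s_i)
    emb <- embed_manifold(snn_smooth(s), seed = s_i)
    pts <- as.matrix(emb[, c("x", "y")])
    expect_true(all(is.finite(pts)))
    d <- as.matrix(dist(pts))
    intra <- c(d[1:6, 1:6][upper.tri(d[1:6, 1:6])], d[7:12, 7:12][upper.tri(d[7:12, 7:12])])
    inter <- as.vector(d[1:6, 7:12])
    if (mean(inter) > mean(intra)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("embedding fewer than three pathways is an error", {
  s <- block_similarity(n = 12)[1:2, 1:2]
  expect_error(embed_manifold(s), "at least 3 pathways")
})

test_that("four well-separated clouds are grouped into four by the eigen-gap", {
  hits <- 0
  for (s_i in 1:10) {
    set.seed(s_i)
    centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
    pts <- do.call(rbind, lapply(1:4, function(b) {
      matrix(rnorm(16, sd = 0.05), 8, 2) + rep(centers[b, ], each = 8)
    }))
    emb <- tibble::tibble(
      pathway = paste0("PW", 1:32), x = pts[, 1], y = pts[, 2]
    )
    grouped <- group_pathways(emb, seed = s_i)
    if (attr(grouped, "n_groups") == 4) {
      tab <- table(grouped$group, rep(1:4, each = 8))
      if (sum(apply(tab, 2, max)) == 32) hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("coincident points collapse to a single group with a warning", {
  emb <- tibble::tibble(pathway = paste0("P", 1:5), x = 1, y = 2)
  expect_warning(grouped <- group_pathways(emb), "single group")
  expect_equal(nlevels(grouped$group), 1)
})

test_that("duplicated datasets land on coincident manifold positions", {
  # with n duplicated networks the duplicate pairs are a 1/(2n - 1) fraction
  # of all pairwise distances, so n >= 11 is needed for the 5th-percentile
  # check to be satisfiable at all
  set.seed(15)
  nets <- lapply(1:12, function(i) {
    adj <- named_adj(4, rbinom(16, 1, 0.5) * runif(16, 0.2, 1))
    diag(adj) <- 0
    net_from_adj(adj, paste0("PW", i))
  })
  names(nets) <- paste0("PW", 1:12)
  emb <- joint_embed(
    list(ds1 = nets, ds2 = nets),
    kind = "functional", seed = 2
  )
  expect_setequal(unique(emb$dataset), c("ds1", "ds2"))
  expect_true(all(table(emb$pathway) == 2))
  d_all <- as.matrix(dist(as.matrix(emb[, c("x", "y")])))
  dup_d <- vapply(paste0("PW", 1:12), function(pw) {
    pathway_distance(emb, pw)
  }, numeric(1))
  q05 <- quantile(d_all[upper.tri(d_all)], 0.05)
  expect_true(all(dup_d <= q05))
})

test_that("functional joint embedding rejects mismatched group sets", {
  n1 <- net_from_adj(named_adj(3, 0.5), "PW1")
  n2 <- net_from_adj(named_adj(4, 0.5), "PW1")
  expect_error(
    joint_embed(list(a = list(PW1 = n1), b = list(PW1 = n2)), kind = "functional"),
    "same cell group"
  )
})

test_that("pathway distances are Euclidean and symmetric in dataset order", {
  emb <- tibble::tibble(
    dataset = c("a", "b"), pathway = c("X", "X"),
    x = c(0, 3), y = c(0, 4)
  )
  expect_equal(pathway_distance(emb, "X"), 5)
  emb2 <- emb[2:1, ]
  expect_equal(pathway_distance(emb2, "X"), 5)
  expect_error(pathway_distance(emb, "Y"), "not shared")
})
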