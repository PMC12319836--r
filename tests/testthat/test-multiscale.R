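test_that("edge scan announces the combinatorial test count and flags dead edges", {
  sim <- make_ie_sample(n = 8, N = 6, delta = 3, seed = 1)
  rep <- edge_scan(sim$sample, method = "permutation", n_permutations = 200,
                   seed = 1)
  expect_equal(attr(rep, "n_tests"), 8 * 7 / 2)
  expect_equal(nrow(rep), 28)
  expect_setequal(rep$rank, 1:28)
  # a sample with an identically-zero edge: skipped and flagged
  A <- random_adjacency(5, seed = 2); A[1, 2] <- A[2, 1] <- 0
  B <- random_adjacency(5, seed = 3); B[1, 2] <- B[2, 1] <- 0
  s <- connectome_sample(list(A, A, B, B), c("a", "a", "b", "b"))
  r2 <- suppressWarnings(edge_scan(s, method = "chi_square"))
  expect_true(r2$skipped[r2$edge == "1--2"])
  expect_true(is.na(r2$p_raw[r2$edge == "1--2"]))
  expect_equal(attr(r2, "n_tests"), 10)
})

test_that("edge scan ranks a strongly planted edge first", {
  hits <- vapply(1:10, function(r) {
    sim <- generate_edge_sim(edge_sim_config(n_vertices = 10, n_per_group = 20,
                                             delta = 3, n_signal = 1,
                                             seed = 100 + r))
    rep <- edge_scan(sim$sample, method = "chi_square")
    top <- rep[rep$rank == 1, ]
    top$i == sim$truth[1, 1] && top$j == sim$truth[1, 2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("edge scan controls FWER under a simulated global null", {
  any_rej <- vapply(1:200, function(r) {
    sim <- generate_edge_sim(edge_sim_config(n_vertices = 8, n_per_group = 12,
                                             delta = 0, phi = 0,
                                             seed = 500 + r))
    rep <- edge_scan(sim$sample, method = "chi_square", correction = "holm")
    any(rep$p_adjusted <= 0.05, na.rm = TRUE)
  }, logical(1))
  fwer <- mean(any_rej)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("scans are equivariant under joint permutation of graphs and labels", {
  sim <- make_ie_sample(n = 6, N = 5, delta = 2, seed = 4)
  s <- sim$sample
  perm <- sample(s$m)
  s2 <- connectome_sample(s$graphs[, , perm], s$labels[perm], validate = FALSE)
  r1 <- suppressWarnings(edge_scan(s, method = "chi_square"))
  r2 <- suppressWarnings(edge_scan(s2, method = "chi_square"))
  expect_equal(r1$statistic[order(r1$edge)], r2$statistic[order(r2$edge)],
               tolerance = 1e-12)
})

test_that("vertex scan reports one test per vertex and finds planted vertices", {
  sim <- generate_vertex_sim(vertex_sim_config(n_signal = 10, seed = 5))
  rep <- vertex_scan(sim$sample, d = 2)
  expect_equal(nrow(rep), 50)
  expect_equal(attr(rep, "n_tests"), 50)
  expect_setequal(rep$vertex, 1:50)
  # planted-signal recovery at a calibrated effect (averaged over replicates)
  prec <- vapply(1:8, function(r) {
    sim <- generate_vertex_sim(vertex_sim_config(n_signal = 10, kind = "stretch",
                                                 stretch = 1.25, seed = 200 + r))
    rep <- vertex_scan(sim$sample, d = 2)
    mean(rep$vertex[rep$rank <= 10] %in% sim$truth)
  }, numeric(1))
  expect_gte(mean(prec), 0.8)
})

test_that("vertex scan makes no discoveries under a global RDPG null", {
  clean <- vapply(1:30, function(r) {
    s <- make_null_rdpg_sample(n = 25, N = 8, seed = 300 + r)
    rep <- vertex_scan(s, d = 2)
    sum(rep$p_adjusted <= 0.05) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("community scan counts K(K+1)/2 blocks including within-community blocks", {
  set.seed(6)
  n <- 28
  tau <- rep(1:14, each = 2)
  graphs <- array(runif(n * n * 6), c(n, n, 6))
  for (g in 1:6) {
    graphs[, , g] <- (graphs[, , g] + t(graphs[, , g])) / 2
    diag(graphs[, , g]) <- 0
  }
  s <- connectome_sample(graphs, rep(c("a", "b"), each = 3), communities = tau,
                         validate = FALSE)
  rep <- suppressWarnings(community_scan(s, approach = "multivariate_weighted",
                                         method = "chi_square"))
  expect_equal(attr(rep, "n_tests"), 14 * 15 / 2)
  expect_equal(nrow(rep), 105)
})

test_that("multivariate weighted community test detects variance-only blocks that scalar means miss", {
  n_rep <- 20
  res <- vapply(1:n_rep, function(r) {
    sim <- generate_community_sim(community_sim_config(n_per_group = 35,
                                                       seed = 700 + r))
    mw <- community_scan(sim$sample, approach = "multivariate_weighted")
    aw <- community_scan(sim$sample, approach = "average_edge_weight")
    c(mw = mw$p_raw[mw$block == "2--2"] <= 0.05,
      aw = aw$p_raw[aw$block == "2--2"] <= 0.05)
  }, logical(2))
  expect_gte(mean(res["mw", ]) - mean(res["aw", ]), 0.3)
  expect_gte(mean(res["mw", ]), 0.7)
})

test_that("community scan stays clean when all blocks are null", {
  clean <- vapply(1:40, function(r) {
    sim <- generate_community_sim(community_sim_config(n_per_group = 25,
                                                       null_all = TRUE,
                                                       seed = 900 + r))
    rep <- community_scan(sim$sample, approach = "multivariate_weighted")
    sum(rep$p_adjusted <= 0.05, na.rm = TRUE) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("global scan separates well-separated populations and flags degenerate input", {
  set.seed(7)
  X1 <- matrix(0.3, 20, 2); X2 <- matrix(0.65, 20, 2)
  graphs <- array(0, c(20, 20, 10))
  for (i in 1:5) graphs[, , i] <- sample_rdpg(X1)
  for (i in 6:10) graphs[, , i] <- sample_rdpg(X2)
  s <- connectome_sample(graphs, rep(c("a", "b"), each = 5), validate = FALSE)
  gs <- global_scan(s, d = 2)
  expect_lt(gs$summary["mean_within"], gs$summary["mean_between"])
  expect_equal(nrow(gs$coordinates), 10)
  expect_false(gs$degenerate)
  # identical graphs: all-zero dissimilarity, degenerate flag
  A <- random_adjacency(8, seed = 8)
  s0 <- connectome_sample(list(A, A, A, A), c("a", "a", "b", "b"))
  gs0 <- global_scan(s0, d = 2)
  expect_true(gs0$degenerate)
  expect_equal(max(gs0$dissimilarity), 0)
})

test_that("bilateral aggregation takes the worse hemisphere and matches brute force", {
  sim <- generate_vertex_sim(vertex_sim_config(n_signal = 10, seed = 9))
  rep <- vertex_scan(sim$sample, d = 2)
  pairs <- cbind(1:25, 26:50)
  agg <- bilateral_aggregate(rep, pairs)
  expect_equal(nrow(agg), 25)
  padj <- rep$p_adjusted[order(rep$vertex)]
  # direct recomputation oracle
  expect_equal(agg$p_pair[order(agg$left)], pmax(padj[1:25], padj[26:50]))
  # a pair with one huge p ranks below a pair with two moderate ps
  toy <- rep[1:4, ]
  toy$vertex <- 1:4
  toy$p_adjusted <- c(1e-10, 0.9, 1e-4, 1e-4)
  attr(toy, "scale") <- "vertex"
  a2 <- bilateral_aggregate(toy, cbind(c(1, 3), c(2, 4)))
  expect_equal(a2$left[a2$rank == 1], 3)
  expect_error(bilateral_aggregate(rep, cbind(c(1, 1), c(2, 3))), "multiple")
})

test_that("component ranking is deterministic with documented tie-breaks", {
  rows <- data.frame(id = c("c", "a", "b"), statistic = c(1, 2, 3),
                     p_raw = c(0.2, 0.1, 0.3))
  expect_equal(rank_components(rows)$id, c("a", "c", "b"))
  ties <- data.frame(id = c("b", "a", "c"), statistic = c(5, 9, 7),
                     p_raw = rep(0.5, 3))
  expect_equal(rank_components(ties)$id, c("a", "c", "b"))
  # reference sort oracle on random tables
  set.seed(10)
  tab <- data.frame(id = sprintf("e%03d", 1:40),
                    statistic = round(rnorm(40), 1),
                    p_raw = round(runif(40), 1))
  got <- rank_components(tab)$id
  oracle <- tab$id[order(tab$p_raw, -tab$statistic, tab$id)]
  expect_equal(got, oracle)
})

test_that("anatomical confounding scan emits one decision per vertex-feature cell", {
  set.seed(11)
  n <- 6; m <- 40
  X <- matrix(0.5, n, 2)
  graphs <- array(0, c(n, n, m))
  for (i in seq_len(m)) graphs[, , i] <- sample_rdpg(X)
  s <- connectome_sample(graphs, rep(c("a", "b"), each = m / 2),
                         validate = FALSE)
  feats <- array(rnorm(m * n * 4), c(m, n, 4))
  out <- anatomical_confounding_scan(s, feats, d = 2, n_permutations = 60,
                                     n_neighbors = 8, seed = 1)
  expect_equal(dim(out$p_adjusted), c(n, 4))
  expect_equal(length(out$n_confounders), n)
  expect_true(all(out$p_adjusted >= 0 & out$p_adjusted <= 1))
  expect_error(anatomical_confounding_scan(s, feats[, 1:3, , drop = FALSE]),
               "match")
})
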