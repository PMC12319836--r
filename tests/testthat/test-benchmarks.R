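test_that("ROC/AUC equals exhaustive pair counting and handles extremes", {
  p <- c(0.01, 0.02, 0.5, 0.6, 0.9)
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  out <- roc_curve_auc(p, truth)
  expect_equal(out$auc, 1)
  expect_equal(max(out$curve$tpr), 1)
  # exhaustive pair-counting oracle (ties count one half)
  set.seed(1)
  p2 <- round(runif(30), 1)
  t2 <- rbinom(30, 1, 0.4) == 1
  pairs <- expand.grid(i = which(t2), j = which(!t2))
  oracle <- mean(ifelse(p2[pairs$i] < p2[pairs$j], 1,
                        ifelse(p2[pairs$i] == p2[pairs$j], 0.5, 0)))
  expect_equal(roc_curve_auc(p2, t2)$auc, oracle, tolerance = 1e-12)
  # uninformative p-values give AUC near one half
  set.seed(2)
  aucs <- replicate(100, roc_curve_auc(runif(60), rep(c(TRUE, FALSE), 30))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(100))
  expect_error(roc_curve_auc(runif(4), rep(TRUE, 4)), "positives and negatives")
})

test_that("precision at k counts signals among the top-ranked components", {
  p <- c(0.01, 0.02, 0.3, 0.4)
  expect_equal(precision_at_k(p, c(TRUE, TRUE, FALSE, FALSE), 2), 1)
  expect_equal(precision_at_k(p, c(FALSE, FALSE, TRUE, TRUE), 2), 0)
  expect_error(precision_at_k(p, rep(TRUE, 4), 0), "positive")
  expect_error(precision_at_k(p, rep(TRUE, 4), 9), "exceeds")
  # brute-force count oracle on random tables with ties
  set.seed(3)
  p2 <- round(runif(50), 1)
  s2 <- rnorm(50)
  t2 <- rbinom(50, 1, 0.3) == 1
  ord <- order(p2, -s2, seq_along(p2))
  expect_equal(precision_at_k(p2, t2, 7, statistic = s2),
               mean(t2[ord[1:7]]))
})

test_that("MDMR pseudo-F matches a direct Gower-trace computation and enumerated permutations", {
  set.seed(4)
  sim <- generate_vertex_sim(vertex_sim_config(n_vertices = 12, n_per_group = 3,
                                               n_signal = 3, stretch = 1.3,
                                               seed = 4))
  s <- sim$sample
  out <- mdmr_vertex_test(s, n_permutations = 2000, seed = 5)
  expect_equal(nrow(out), 12)
  # oracle for vertex 1: direct pseudo-F from the Gower-centered matrix
  prof <- t(s$graphs[1, , ])
  D <- as.matrix(dist(prof))
  G <- -0.5 * D^2
  G <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G)) + mean(G)
  lab <- as.integer(s$labels)
  trHG <- sum(G[lab == 1, lab == 1]) / 3 + sum(G[lab == 2, lab == 2]) / 3
  f_oracle <- trHG / ((sum(diag(G)) - trHG) / (6 - 2))
  expect_equal(out$statistic[1], f_oracle, tolerance = 1e-10)
  # exhaustive permutation oracle over all 20 balanced relabelings
  combs <- combn(6, 3)
  fs <- apply(combs, 2, function(ix) {
    lb <- rep(2, 6); lb[ix] <- 1
    tr <- sum(G[lb == 1, lb == 1]) / 3 + sum(G[lb == 2, lb == 2]) / 3
    tr / ((sum(diag(G)) - tr) / 4)
  })
  p_exact <- mean(fs >= f_oracle - 1e-12)
  expect_lt(abs(out$p_raw[1] - p_exact), 0.05)
})

test_that("MDMR flags identical subjects and detects strong profile shifts", {
  A <- random_adjacency(10, seed = 6)
  s <- connectome_sample(list(A, A, A, A, A, A), rep(c("a", "b"), each = 3))
  out <- mdmr_vertex_test(s, n_permutations = 100, seed = 1)
  expect_true(all(out$p_raw > 0.9))
  hits <- vapply(1:10, function(r) {
    set.seed(r)
    g1 <- lapply(1:6, function(i) random_adjacency(10, seed = 50 * r + i))
    g2 <- lapply(g1, function(A) { B <- A + 2; diag(B) <- 0; B })
    s2 <- connectome_sample(c(g1, g2), rep(c("a", "b"), each = 6))
    md <- mdmr_vertex_test(s2, n_permutations = 200, seed = r)
    all(md$p_raw < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("NBS finds planted clusters and stays calibrated under the null", {
  # planted dense cluster of strong edges
  set.seed(7)
  base <- matrix(0.3, 20, 2)
  strong <- base; strong[1:6, ] <- 0.62
  g1 <- lapply(1:8, function(i) sample_rdpg(base))
  g2 <- lapply(1:8, function(i) sample_rdpg(strong))
  s <- connectome_sample(c(g1, g2), rep(c("a", "b"), each = 8),
                         validate = FALSE)
  out <- nbs_scan(s, "t_test", n_permutations = 150, seed = 2)
  expect_lt(max(out$vertex_p[1:6]), min(1, min(out$vertex_p[7:20]) + 1e-12))
  expect_equal(min(out$components$p), min(out$vertex_p))
  # null calibration: smallest component p rarely below alpha
  ok <- vapply(1:20, function(r) {
    s0 <- make_null_rdpg_sample(n = 15, N = 6, seed = 400 + r)
    o <- suppressWarnings(nbs_scan(s0, "t_test", n_permutations = 150,
                                   seed = r))
    nrow(o$components) == 0 || min(o$components$p) >= 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.8)
  # an unreachable fixed threshold empties the graph
  expect_warning(o0 <- nbs_scan(s, "t_test", primary_threshold = 1e6,
                                n_permutations = 50, seed = 1),
                 "no edges survive")
  expect_true(all(o0$vertex_p == 1))
})

test_that("vertex graph statistics match closed forms on canonical graphs", {
  K4 <- 1 - diag(4)
  st <- vertex_graph_statistics(K4)
  expect_equal(unname(st[, "degree"]), rep(3, 4))
  expect_equal(unname(st[, "clustering"]), rep(1, 4))
  expect_equal(unname(st[, "triangles"]), rep(3, 4))
  expect_equal(unname(st[, "betweenness"]), rep(0, 4))
  expect_equal(colnames(st),
               c("degree", "clustering", "betweenness", "closeness", "triangles"))
  # star graph: center betweenness (n-1)(n-2)/2, leaves 0
  n <- 7
  star <- matrix(0, n, n); star[1, 2:n] <- star[2:n, 1] <- 1
  sb <- vertex_graph_statistics(star)
  expect_equal(sb[1, "betweenness"], (n - 1) * (n - 2) / 2, ignore_attr = TRUE)
  expect_equal(unname(sb[2:n, "betweenness"]), rep(0, n - 1))
  expect_equal(unname(sb[2:n, "triangles"]), rep(0, n - 1))
  # triangles agree with the A^3 diagonal oracle on a random graph
  set.seed(8)
  A <- (random_adjacency(12, seed = 8) > 0.5) * 1
  tri_oracle <- diag(A %*% A %*% A) / 2
  expect_equal(unname(vertex_graph_statistics(A)[, "triangles"]), tri_oracle)
  # weighted degree column keeps the raw strengths
  W <- random_adjacency(6, seed = 9)
  expect_equal(unname(vertex_graph_statistics(W)[, "degree"]), rowSums(W))
})

test_that("graph-statistic vertex test degenerates to p = 1 on identical graphs", {
  A <- (random_adjacency(10, seed = 10) > 0.5) * 1
  s <- connectome_sample(list(A, A, A, A, A, A), rep(c("a", "b"), each = 3))
  out <- suppressWarnings(ergm_stats_vertex_test(s))
  expect_true(all(out$p_raw == 1))
  expect_equal(nrow(out), 10)
})

test_that("edge benchmark grids are filled, bounded, and seed-reproducible", {
  b1 <- run_edge_benchmark(deltas = 1, phis = 2, sample_sizes = 10,
                           n_replicates = 3, n_vertices = 10, n_signal = 5,
                           k = 5, seed = 21)
  expect_equal(nrow(b1$results), 2 * 3 * 3)  # 2 cells x 3 reps x 3 methods
  expect_true(all(b1$results$precision >= 0 & b1$results$precision <= 1))
  b2 <- run_edge_benchmark(deltas = 1, phis = 2, sample_sizes = 10,
                           n_replicates = 3, n_vertices = 10, n_signal = 5,
                           k = 5, seed = 21)
  expect_identical(b1$results, b2$results)
})

test_that("community benchmark tallies per-block error rates", {
  bm <- run_community_benchmark(sample_sizes = 20, n_replicates = 4, seed = 31)
  expect_equal(nrow(bm$results), 4 * 4 * 3)  # approaches x reps x blocks
  expect_true(all(bm$summary$rate >= 0 & bm$summary$rate <= 1))
  expect_setequal(unique(bm$summary$metric[bm$summary$block == 1]), "fpr")
})

test_that("vertex benchmark returns one AUC per method, setting, and replicate", {
  bm <- run_vertex_benchmark(methods = c("omni", "mdmr"), n_signal_grid = 10,
                             kinds = "stretch", n_replicates = 2,
                             n_permutations_mdmr = 60, seed = 41)
  expect_equal(nrow(bm$results), 4)
  expect_true(all(bm$results$auc >= 0 & bm$results$auc <= 1))
  bm2 <- run_vertex_benchmark(methods = c("omni", "mdmr"), n_signal_grid = 10,
                              kinds = "stretch", n_replicates = 2,
                              n_permutations_mdmr = 60, seed = 41)
  expect_identical(bm$results, bm2$results)
})
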