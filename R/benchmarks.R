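# Benchmark metrics, competitor vertex methods (MDMR, NBS, graph-statistic
# profiles), and the three simulation benchmark drivers.

#' ROC curve and AUC from p-values against a planted truth
#'
#' Sweeps the p-value threshold and records the true/false positive rates;
#' the AUC is computed by the tie-aware Mann-Whitney formulation (equivalent
#' to the trapezoid rule with tied p-values rank-averaged).
#'
#' @param pvalues numeric vector (smaller = stronger evidence of signal).
#' @param truth logical vector, TRUE for planted signal components.
#' @return list with `curve` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_curve_auc <- function(pvalues, truth) {
  truth <- as.logical(truth)
  stopifnot(length(pvalues) == length(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("truth must contain positives and negatives")
  r <- rank(-pvalues, ties.method = "average")
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(pvalues))
  curve <- data.frame(
    threshold = c(-Inf, thr),
    tpr = c(0, vapply(thr, function(t) sum(truth & pvalues <= t) / n1, numeric(1))),
    fpr = c(0, vapply(thr, function(t) sum(!truth & pvalues <= t) / n0, numeric(1))))
  list(curve = curve, auc = auc)
}

#' Precision at k
#'
#' Fraction of the `k` top-ranked components (ascending p, ties broken by
#' descending statistic, then index) that are planted signals.
#'
#' @param pvalues numeric vector.
#' @param truth logical vector.
#' @param k number of top components to inspect.
#' @param statistic optional statistic used for tie-breaking.
#' @return precision in `[0, 1]`.
#' @export
precision_at_k <- function(pvalues, truth, k, statistic = NULL) {
  if (k <= 0) stop("k must be positive")
  if (k > length(pvalues)) stop("k exceeds the number of components")
  if (is.null(statistic)) statistic <- -seq_along(pvalues)
  ord <- order(pvalues, -statistic, seq_along(pvalues), method = "radix")
  mean(as.logical(truth)[ord[seq_len(k)]])
}

# ---- competitor vertex representations ----------------------------------

#' Multivariate distance matrix regression per vertex
#'
#' Represents each vertex by its vector of adjacent edge weights, builds the
#' subjects-by-subjects Euclidean distance matrix, Gower-centers it, and
#' tests group association with the pseudo-F statistic of the group-label
#' hat matrix; the p-value comes from label permutations.
#'
#' @param sample a [connectome_sample()].
#' @param n_permutations permutation count.
#' @param seed optional seed.
#' @return data.frame with one row per vertex: `statistic`, `p_raw`.
#' @export
mdmr_vertex_test <- function(sample, n_permutations = 500, seed = NULL) {
  check_group_sizes(sample$labels)
  m <- sample$m; n <- sample$n
  labels <- as.integer(sample$labels)
  k <- max(labels)
  sizes <- tabulate(labels, k)
  if (!is.null(seed)) set.seed(seed)
  # indicator matrices for the observed and permuted labelings
  perm_idx <- cbind(seq_len(m),
                    replicate(n_permutations, sample.int(m)))
  stat <- numeric(n); praw <- numeric(n)
  J <- matrix(1 / m, m, m)
  for (v in seq_len(n)) {
    prof <- t(sample$graphs[v, , , drop = TRUE])       # m x n adjacent weights
    D <- as.matrix(dist(prof))
    A <- -0.5 * D^2
    G <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
    trG <- sum(diag(G))
    # tr(HG) for each labeling; Gower centering kills the intercept term
    trHG <- vapply(seq_len(ncol(perm_idx)), function(b) {
      lb <- labels[perm_idx[, b]]
      s <- 0
      for (g in seq_len(k)) {
        ix <- which(lb == g)
        s <- s + sum(G[ix, ix]) / sizes[g]
      }
      s
    }, numeric(1))
    fs <- (trHG / (k - 1)) / pmax((trG - trHG) / (m - k), .Machine$double.eps)
    stat[v] <- fs[1]
    praw[v] <- (1 + sum(fs[-1] >= fs[1] - 1e-12)) / (n_permutations + 1)
    if (trG <= 1e-12) { stat[v] <- 0; praw[v] <- 1 }  # identical subjects
  }
  data.frame(vertex = seq_len(n), statistic = stat, p_raw = praw)
}

# pooled two-sample |t| statistics for every column of W (subjects x edges)
edge_tstats <- function(W, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- colMeans(W[g1, , drop = FALSE]); m2 <- colMeans(W[g2, , drop = FALSE])
  v1 <- colSums(sweep(W[g1, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(W[g2, , drop = FALSE], 2, m2)^2)
  sp <- sqrt((v1 + v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  abs(m1 - m2) / pmax(sp, .Machine$double.eps)
}

#' Network-based statistic scan
#'
#' Computes a per-edge group-difference statistic (pooled two-sample |t| or
#' the unbiased k-sample Dcorr), keeps edges above a primary threshold,
#' finds the connected components of the supra-threshold graph, and
#' calibrates each observed component's extent (edge count) against the
#' permutation null of the maximum component extent. Each vertex inherits
#' the p-value of the supra-threshold component containing it; vertices in
#' none get p = 1.
#'
#' The default primary threshold is the 95th percentile of the pooled
#' permutation distribution of the edge statistic, giving a fixed,
#' reproducible rule.
#'
#' @param sample a two-group [connectome_sample()].
#' @param edge_stat `"t_test"` or `"dcorr"`.
#' @param primary_threshold fixed threshold; `NULL` uses the permutation
#'   quantile.
#' @param threshold_quantile quantile of the permuted edge statistics used
#'   when `primary_threshold` is `NULL`.
#' @param n_permutations permutation count (shared by thresholding and the
#'   component null).
#' @param seed optional seed.
#' @return list with `components` (data.frame: id, n_vertices, n_edges,
#'   p), `vertex_p` (length-n vector), `threshold`.
#' @export
nbs_scan <- function(sample, edge_stat = c("t_test", "dcorr"),
                     primary_threshold = NULL, threshold_quantile = 0.95,
                     n_permutations = 200, seed = NULL) {
  edge_stat <- match.arg(edge_stat)
  check_group_sizes(sample$labels)
  labels <- as.integer(sample$labels)
  if (edge_stat == "t_test" && max(labels) != 2)
    stop("the t-test edge statistic needs exactly two groups")
  ew <- edge_weight_matrix(sample)
  m <- sample$m; n <- sample$n; E <- ncol(ew$W)
  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_permutations, sample.int(m))
  if (edge_stat == "t_test") {
    stat_for <- function(lb) edge_tstats(ew$W, which(lb == 1), which(lb == 2))
    obs <- stat_for(labels)
    perm_stats <- vapply(seq_len(n_permutations),
                         function(b) stat_for(labels[perms[, b]]), numeric(E))
  } else {
    sc <- scalar_ucentered(ew$W)
    Uy <- ucenter(label_distance(labels))
    vy <- sum(Uy^2)
    denom <- sqrt(sc$vx * vy)
    sfun <- function(idx) {
      uy <- as.vector(Uy[idx, idx])
      s <- as.vector(crossprod(sc$U, uy))
      ifelse(denom > 0, s / denom, 0)
    }
    obs <- sfun(seq_len(m))
    perm_stats <- vapply(seq_len(n_permutations),
                         function(b) sfun(perms[, b]), numeric(E))
  }
  thr <- if (is.null(primary_threshold))
    quantile(perm_stats, threshold_quantile, names = FALSE)
  else primary_threshold
  comp_extent <- function(st) {
    keep <- which(st > thr)
    if (!length(keep)) return(list(max = 0, membership = NULL, keep = keep))
    g <- igraph::graph_from_edgelist(cbind(ew$i[keep], ew$j[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    cs <- igraph::components(g)
    # extent = number of supra-threshold edges per component
    ecomp <- cs$membership[ew$i[keep]]
    ext <- tabulate(ecomp, cs$no)
    list(max = max(ext), membership = cs$membership, extent = ext, keep = keep)
  }
  obs_comp <- comp_extent(obs)
  null_max <- vapply(seq_len(n_permutations),
                     function(b) comp_extent(perm_stats[, b])$max, numeric(1))
  vertex_p <- rep(1, n)
  comps <- data.frame(id = integer(0), n_vertices = integer(0),
                      n_edges = integer(0), p = numeric(0))
  if (obs_comp$max == 0) {
    warning("no edges survive the primary threshold; all vertex p-values are 1")
  } else {
    live <- which(obs_comp$extent > 0)
    for (cid in live) {
      pc <- (1 + sum(null_max >= obs_comp$extent[cid])) / (n_permutations + 1)
      vids <- which(obs_comp$membership == cid)
      comps <- rbind(comps, data.frame(id = cid, n_vertices = length(vids),
                                       n_edges = obs_comp$extent[cid], p = pc))
      vertex_p[vids] <- pmin(vertex_p[vids], pc)
    }
  }
  list(components = comps, vertex_p = vertex_p, threshold = thr,
       edge_stat = edge_stat, n_permutations = n_permutations)
}

#' Vertex-level graph statistics
#'
#' Per vertex: weighted degree (strength), local clustering coefficient,
#' betweenness centrality, closeness centrality, and triangle count.
#' All but the degree are computed on the Otsu-binarized graph; for
#' disconnected graphs the closeness column switches to the harmonic
#' (per-component) variant and the result carries attribute
#' `disconnected = TRUE`.
#'
#' @param A weighted adjacency matrix.
#' @return `n x 5` matrix with columns degree, clustering, betweenness,
#'   closeness, triangles.
#' @export
vertex_graph_statistics <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  vals <- A[A > 0]
  bin <- if (length(unique(vals)) >= 2 && any(A != (A > 0)))
    otsu_binarize(A, otsu_threshold(vals)) else (A > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(bin, mode = "undirected")
  disconnected <- !igraph::is_connected(g)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  btw <- igraph::betweenness(g)
  clo <- if (disconnected) {
    igraph::harmonic_centrality(g, normalized = TRUE)
  } else {
    suppressWarnings(igraph::closeness(g, normalized = TRUE))
  }
  clo[!is.finite(clo)] <- 0
  tri <- igraph::count_triangles(g)
  out <- cbind(degree = rowSums(A), clustering = cl, betweenness = btw,
               closeness = clo, triangles = tri)
  attr(out, "disconnected") <- disconnected
  out
}

#' Graph-statistic vertex test
#'
#' Represents each vertex of each subject by the five-dimensional vector of
#' graph statistics from [vertex_graph_statistics()] and compares groups per
#' vertex with Hotelling's T-squared (two groups) or MANOVA with Pillai's
#' trace. Statistic dimensions that are constant across all subjects at a
#' vertex are dropped with a warning; a vertex with no varying dimension
#' gets p = 1.
#'
#' @param sample a [connectome_sample()].
#' @return data.frame with one row per vertex: `statistic`, `p_raw`.
#' @export
ergm_stats_vertex_test <- function(sample) {
  check_group_sizes(sample$labels)
  m <- sample$m; n <- sample$n
  stats_arr <- array(0, c(m, n, 5))
  for (g in seq_len(m))
    stats_arr[g, , ] <- vertex_graph_statistics(sample$graphs[, , g])
  lv <- levels(sample$labels)
  stat <- numeric(n); praw <- numeric(n)
  dropped_any <- FALSE
  for (v in seq_len(n)) {
    Xv <- stats_arr[, v, , drop = TRUE]
    keep <- apply(Xv, 2, function(col) sd(col) > 1e-12)
    if (!any(keep)) { stat[v] <- 0; praw[v] <- 1; next }
    if (!all(keep)) dropped_any <- TRUE
    Xv <- Xv[, keep, drop = FALSE]
    groups <- lapply(lv, function(l) Xv[sample$labels == l, , drop = FALSE])
    out <- tryCatch({
      if (length(lv) == 2) hotelling_t2(groups[[1]], groups[[2]])
      else manova_pillai(groups)
    }, error = function(e) test_outcome(0, 1, "degenerate"))
    stat[v] <- out$statistic
    praw[v] <- out$p_raw
  }
  if (dropped_any)
    warning("constant graph-statistic dimensions dropped at some vertices")
  data.frame(vertex = seq_len(n), statistic = stat, p_raw = praw)
}

# ---- benchmark drivers --------------------------------------------------

# vectorized per-edge p-values for the three edge-benchmark tests
edge_benchmark_pvalues <- function(W, labels, test) {
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  n1 <- length(g1); n2 <- length(g2)
  if (test == "t_test") {
    tt <- edge_tstats(W, g1, g2)
    return(2 * stats::pt(tt, df = n1 + n2 - 2, lower.tail = FALSE))
  }
  if (test == "mann_whitney") {
    # normal approximation with tie correction, adequate for ranking edges
    R <- apply(W, 2, rank)
    U <- colSums(R[g1, , drop = FALSE]) - n1 * (n1 + 1) / 2
    ties <- apply(W, 2, function(w) {
      tb <- table(w); sum(tb^3 - tb)
    })
    nn <- n1 + n2
    sig <- sqrt(n1 * n2 / 12 * ((nn + 1) - ties / (nn * (nn - 1))))
    z <- abs(U - n1 * n2 / 2) / pmax(sig, .Machine$double.eps)
    return(2 * pnorm(z, lower.tail = FALSE))
  }
  if (test == "dcorr") {
    res <- dcorr_scan_scalar(W, labels, method = "auto", n_permutations = 300)
    return(res$p_raw)
  }
  stop("unknown test")
}

#' Edge-scale simulation benchmark
#'
#' For each grid cell (mean shift `delta` or variance inflation `phi`,
#' crossed with per-group sample size) and each replicate, generates a
#' two-population weighted independent-edge sample with planted signal
#' edges, computes per-edge p-values under the pooled t-test, the
#' Mann-Whitney U test, and the k-sample Dcorr test, and scores
#' precision-at-k against the planted truth.
#'
#' @param deltas mean shifts evaluated with `phi = 0`.
#' @param phis variance inflations evaluated with `delta = 0`.
#' @param sample_sizes per-group sizes N.
#' @param n_replicates replicates per cell.
#' @param k precision cutoff (default 10).
#' @param n_vertices,n_signal simulation geometry.
#' @param seed master seed.
#' @return list with `results` (tidy per-replicate data.frame) and
#'   `summary` (mean precision per cell and method).
#' @export
run_edge_benchmark <- function(deltas = c(0.5, 1, 2), phis = c(1, 2, 3),
                               sample_sizes = c(10, 20, 30),
                               n_replicates = 50, k = 10, n_vertices = 20,
                               n_signal = 10, seed = 1) {
  cells <- rbind(
    data.frame(setting = "mean_shift", delta = deltas, phi = 0),
    data.frame(setting = "variance_shift", delta = 0, phi = phis))
  cells <- merge(cells, data.frame(N = sample_sizes))
  methods <- c("t_test", "mann_whitney", "dcorr")
  out <- vector("list", nrow(cells) * n_replicates)
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (r in seq_len(n_replicates)) {
      cfg <- edge_sim_config(n_vertices = n_vertices, n_per_group = cells$N[ci],
                             delta = cells$delta[ci], phi = cells$phi[ci],
                             n_signal = n_signal,
                             seed = derive_seed(seed, ci, r))
      sim <- generate_edge_sim(cfg)
      ew <- edge_weight_matrix(sim$sample)
      truth <- rep(FALSE, ncol(ew$W))
      utidx <- which(upper.tri(matrix(0, n_vertices, n_vertices)))
      truth_lin <- sim$truth[, 1] + (sim$truth[, 2] - 1) * n_vertices
      truth[match(truth_lin, utidx)] <- TRUE
      prec <- vapply(methods, function(mt) {
        p <- edge_benchmark_pvalues(ew$W, sim$sample$labels, mt)
        precision_at_k(p, truth, k)
      }, numeric(1))
      row <- row + 1L
      out[[row]] <- data.frame(setting = cells$setting[ci],
                               delta = cells$delta[ci], phi = cells$phi[ci],
                               N = cells$N[ci], replicate = r,
                               method = methods, precision = unname(prec))
    }
  }
  results <- do.call(rbind, out)
  summary <- aggregate(precision ~ setting + delta + phi + N + method,
                       data = results, FUN = mean)
  list(results = results, summary = summary)
}

#' Vertex-scale simulation benchmark
#'
#' For each perturbation setting (stretch; rotate-and-stretch), signal-count
#' grid value, and replicate, generates a two-population RDPG sample with
#' planted signal vertices and scores each requested vertex representation
#' by the area under its ROC curve (per-vertex p-values against the planted
#' truth): `omni` (omnibus embedding + Hotelling), `mdmr`, `ergm_stats`,
#' `nbs_t`, and `nbs_dcorr`.
#'
#' @param methods subset of the five method tags above.
#' @param n_signal_grid planted signal-vertex counts.
#' @param kinds perturbation settings to include.
#' @param n_per_group graphs per group.
#' @param n_replicates replicates per (kind, n_signal) setting.
#' @param d embedding dimension for the omni method.
#' @param n_permutations_nbs,n_permutations_mdmr permutation counts.
#' @param seed master seed.
#' @return list with `results` (tidy per-replicate AUC) and `summary`
#'   (mean AUC per method, plus per-setting breakdown).
#' @export
run_vertex_benchmark <- function(methods = c("omni", "mdmr", "ergm_stats",
                                             "nbs_t", "nbs_dcorr"),
                                 n_signal_grid = c(5, 10, 15, 20, 25),
                                 kinds = c("stretch", "rotate_and_stretch"),
                                 n_per_group = 8, n_replicates = 25, d = 2,
                                 n_permutations_nbs = 200,
                                 n_permutations_mdmr = 200, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list(); row <- 0L
  for (ki in seq_along(kinds)) for (si in seq_along(n_signal_grid)) {
    for (r in seq_len(n_replicates)) {
      cfg <- vertex_sim_config(n_per_group = n_per_group,
                               n_signal = n_signal_grid[si], kind = kinds[ki],
                               seed = derive_seed(seed, ki, si, r))
      sim <- generate_vertex_sim(cfg)
      truth <- seq_len(sim$sample$n) %in% sim$truth
      # per-method p-vectors on the shared simulated sample
      pv <- list()
      if ("omni" %in% methods) {
        rep_omni <- vertex_scan(sim$sample, d = d)
        pv$omni <- rep_omni$p_raw[order(rep_omni$vertex)]
      }
      if ("mdmr" %in% methods) {
        md <- mdmr_vertex_test(sim$sample, n_permutations = n_permutations_mdmr,
                               seed = derive_seed(seed, ki, si, r, 1))
        pv$mdmr <- md$p_raw
      }
      if ("ergm_stats" %in% methods)
        pv$ergm_stats <- suppressWarnings(ergm_stats_vertex_test(sim$sample))$p_raw
      if ("nbs_t" %in% methods)
        pv$nbs_t <- suppressWarnings(
          nbs_scan(sim$sample, "t_test", n_permutations = n_permutations_nbs,
                   seed = derive_seed(seed, ki, si, r, 2)))$vertex_p
      if ("nbs_dcorr" %in% methods)
        pv$nbs_dcorr <- suppressWarnings(
          nbs_scan(sim$sample, "dcorr", n_permutations = n_permutations_nbs,
                   seed = derive_seed(seed, ki, si, r, 3)))$vertex_p
      for (mt in methods) {
        row <- row + 1L
        out[[row]] <- data.frame(kind = kinds[ki], n_signal = n_signal_grid[si],
                                 replicate = r, method = mt,
                                 auc = roc_curve_auc(pv[[mt]], truth)$auc)
      }
    }
  }
  results <- do.call(rbind, out)
  summary <- aggregate(auc ~ method, data = results, FUN = mean)
  by_setting <- aggregate(auc ~ method + kind + n_signal, data = results,
                          FUN = mean)
  list(results = results, summary = summary, by_setting = by_setting)
}

#' Community-scale simulation benchmark
#'
#' For each per-group sample size and replicate, generates the 3-community
#' block-diagonal weighted SBM simulation and records, for each of the four
#' community approaches, whether each diagonal block is declared signal at
#' level `alpha` (raw per-block p-values). Block 1 is null, so its
#' rejection rate is the false positive rate; blocks 2 (equal mean, unequal
#' variance) and 3 (mean shift) give true positive rates.
#'
#' @param sample_sizes per-group sizes N.
#' @param n_replicates replicates per N.
#' @param alpha decision level.
#' @param config_args extra arguments passed to [community_sim_config()].
#' @param seed master seed.
#' @return list with `results` (tidy rejections) and `summary` (FPR/TPR per
#'   N, approach, block).
#' @export
run_community_benchmark <- function(sample_sizes = c(10, 20, 30, 40, 50),
                                    n_replicates = 50, alpha = 0.05,
                                    config_args = list(), seed = 1) {
  approaches <- c("average_connectivity", "average_edge_weight",
                  "multivariate_binary", "multivariate_weighted")
  out <- list(); row <- 0L
  for (ni in seq_along(sample_sizes)) for (r in seq_len(n_replicates)) {
    cfg <- do.call(community_sim_config,
                   c(list(n_per_group = sample_sizes[ni],
                          seed = derive_seed(seed, ni, r)), config_args))
    sim <- generate_community_sim(cfg)
    for (ap in approaches) {
      rep_ap <- suppressWarnings(
        community_scan(sim$sample, approach = ap, method = "auto",
                       n_permutations = 300,
                       seed = derive_seed(seed, ni, r, match(ap, approaches))))
      diag_rows <- rep_ap[rep_ap$k == rep_ap$l, ]
      for (b in 1:3) {
        row <- row + 1L
        pb <- diag_rows$p_raw[diag_rows$k == b]
        out[[row]] <- data.frame(N = sample_sizes[ni], replicate = r,
                                 approach = ap, block = b,
                                 p = pb, reject = pb <= alpha)
      }
    }
  }
  results <- do.call(rbind, out)
  summary <- aggregate(reject ~ N + approach + block, data = results, FUN = mean)
  names(summary)[names(summary) == "reject"] <- "rate"
  summary$metric <- ifelse(summary$block == 1, "fpr", "tpr")
  list(results = results, summary = summary, alpha = alpha)
}
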