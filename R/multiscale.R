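# The four scan pipelines (edge, vertex, community, global), deterministic
# component ranking, bilateral aggregation, and the anatomical-confounding
# analysis.

# assemble a scan_report data.frame with metadata attributes
new_scan_report <- function(rows, scale, alpha, correction, n_tests) {
  structure(rows, scale = scale, alpha = alpha, correction = correction,
            n_tests = n_tests, class = c("scan_report", "data.frame"))
}

#' @export
print.scan_report <- function(x, n = 10, ...) {
  cat(sprintf("scan_report (%s scale): %d tests, correction = %s, alpha = %g\n",
              attr(x, "scale"), attr(x, "n_tests"), attr(x, "correction"),
              attr(x, "alpha")))
  nrej <- sum(x$p_adjusted <= attr(x, "alpha"), na.rm = TRUE)
  cat(sprintf("rejections after correction: %d\n", nrej))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Rank components by evidence strength
#'
#' Ascending raw p-value, ties broken by descending statistic, then by
#' component identifier; the result is deterministic.
#'
#' @param rows data.frame with columns `p_raw`, `statistic`, and a first
#'   column serving as component identifier.
#' @return `rows`, reordered, with a `rank` column (1 = strongest signal).
#' @export
rank_components <- function(rows) {
  id <- as.character(rows[[1]])
  ord <- order(rows$p_raw, -rows$statistic, id, method = "radix")
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

# flatten the upper triangle of every graph into a subjects x edges matrix
edge_weight_matrix <- function(sample) {
  n <- sample$n; m <- sample$m
  ut <- which(upper.tri(matrix(0, n, n)))
  W <- matrix(0, m, length(ut))
  for (g in seq_len(m)) W[g, ] <- sample$graphs[, , g][ut]
  list(W = W, i = row(matrix(0, n, n))[ut], j = col(matrix(0, n, n))[ut])
}

#' Edge scan: k-sample Dcorr test at every edge
#'
#' For each unordered vertex pair, tests whether the edge-weight
#' distribution is identical across phenotype groups with the k-sample
#' distance correlation, then applies the chosen multiplicity correction
#' and ranks edges by evidence strength. Edges whose weight is zero in every
#' graph are skipped and flagged (they carry no information), but still
#' count toward the announced number of tests.
#'
#' @param sample a [connectome_sample()].
#' @param alpha significance level.
#' @param correction see [adjust_pvalues()].
#' @param method,n_permutations,seed passed to the Dcorr engine.
#' @return a `scan_report` with one row per edge.
#' @export
edge_scan <- function(sample, alpha = 0.05, correction = "holm",
                      method = "auto", n_permutations = 1000, seed = NULL) {
  check_group_sizes(sample$labels)
  ew <- edge_weight_matrix(sample)
  E <- ncol(ew$W)
  zero <- colSums(ew$W != 0) == 0
  stat <- rep(NA_real_, E); praw <- rep(NA_real_, E)
  if (any(!zero)) {
    res <- dcorr_scan_scalar(ew$W[, !zero, drop = FALSE], sample$labels,
                             method = method, n_permutations = n_permutations,
                             seed = seed)
    stat[!zero] <- res$statistic
    praw[!zero] <- res$p_raw
  }
  padj <- rep(NA_real_, E)
  padj[!zero] <- adjust_pvalues(praw[!zero], correction)
  rows <- data.frame(edge = paste0(ew$i, "--", ew$j), i = ew$i, j = ew$j,
                     statistic = stat, p_raw = praw, p_adjusted = padj,
                     skipped = zero)
  tested <- rank_components(rows[!zero, , drop = FALSE])
  if (any(zero)) {
    sk <- rows[zero, , drop = FALSE]
    sk$rank <- nrow(tested) + seq_len(nrow(sk))
    tested <- rbind(tested, sk)
  }
  new_scan_report(tested, "edge", alpha, correction, n_tests = E)
}

#' Vertex scan: omnibus embedding plus Hotelling / MANOVA at every vertex
#'
#' Jointly embeds all graphs with the omnibus embedding, then for each
#' vertex compares its estimated latent positions across phenotype groups:
#' Hotelling's T-squared for two groups, one-way MANOVA with Pillai's trace
#' for more. One test per vertex; corrected and ranked.
#'
#' @param sample a [connectome_sample()].
#' @param d embedding dimension (`NULL` selects it from the omnibus scree).
#' @param alpha significance level.
#' @param correction see [adjust_pvalues()].
#' @param embedding optionally, a precomputed `latent_positions` object.
#' @return a `scan_report` with one row per vertex.
#' @export
vertex_scan <- function(sample, d = NULL, alpha = 0.05, correction = "holm",
                        embedding = NULL) {
  tab <- check_group_sizes(sample$labels)
  if (is.null(embedding)) embedding <- omnibus_embedding(sample$graphs, d = d)
  d <- embedding$d
  if (d >= min(tab) * 2 && length(tab) == 2)
    stop("embedding dimension too large for the group sizes; lower d")
  n <- sample$n
  lv <- levels(sample$labels)
  stat <- numeric(n); praw <- numeric(n)
  for (v in seq_len(n)) {
    Xi <- t(vapply(embedding$positions, function(P) P[v, ], numeric(d)))
    groups <- lapply(lv, function(l) Xi[sample$labels == l, , drop = FALSE])
    out <- if (length(lv) == 2) hotelling_t2(groups[[1]], groups[[2]])
           else manova_pillai(groups)
    stat[v] <- out$statistic
    praw[v] <- out$p_raw
  }
  rows <- data.frame(vertex = seq_len(n), statistic = stat, p_raw = praw,
                     p_adjusted = adjust_pvalues(praw, correction))
  new_scan_report(rank_components(rows), "vertex", alpha, correction, n)
}

# vertex-pair index sets for each community block (k <= l); undirected
community_block_indices <- function(tau) {
  K <- max(tau)
  n <- length(tau)
  ut <- which(upper.tri(matrix(0, n, n)))
  bi <- pmin(tau[row(matrix(0, n, n))[ut]], tau[col(matrix(0, n, n))[ut]])
  bj <- pmax(tau[row(matrix(0, n, n))[ut]], tau[col(matrix(0, n, n))[ut]])
  blocks <- list()
  for (k in seq_len(K)) for (l in k:K) {
    blocks[[paste(k, l, sep = "--")]] <-
      list(k = k, l = l, idx = which(bi == k & bj == l))
  }
  blocks
}

#' Community scan: block-level k-sample tests
#'
#' For every community pair (within-community blocks included), compares
#' the block's connectivity across phenotype groups with one of four
#' approaches: `average_connectivity` (Otsu-binarize, pool per-group
#' nonzero-edge counts, Pearson chi-squared), `average_edge_weight`
#' (per-subject block mean, scalar Dcorr), `multivariate_binary`
#' (Otsu-binarize and vectorize the block, Dcorr), or
#' `multivariate_weighted` (vectorize the weighted block, Dcorr). The Otsu
#' threshold is computed once from the pooled nonzero weights of the whole
#' sample so that "connected" means the same thing for every subject
#' (per-subject thresholding available via `pooled_threshold = FALSE`).
#'
#' @param sample a [connectome_sample()] with communities attached (or pass
#'   `tau`).
#' @param tau optional community assignment overriding the sample's.
#' @param approach one of the four approaches above.
#' @param alpha significance level.
#' @param correction see [adjust_pvalues()].
#' @param method,n_permutations,seed Dcorr engine options.
#' @param pooled_threshold compute one Otsu threshold from the pooled
#'   sample (default) rather than per subject.
#' @return a `scan_report` with one row per community pair; empty blocks are
#'   skipped and flagged.
#' @export
community_scan <- function(sample, tau = NULL,
                           approach = c("multivariate_weighted",
                                        "average_connectivity",
                                        "average_edge_weight",
                                        "multivariate_binary"),
                           alpha = 0.05, correction = "holm", method = "auto",
                           n_permutations = 1000, seed = NULL,
                           pooled_threshold = TRUE) {
  approach <- match.arg(approach)
  check_group_sizes(sample$labels)
  if (is.null(tau)) tau <- sample$communities
  if (is.null(tau)) stop("a community assignment is required")
  ew <- edge_weight_matrix(sample)
  blocks <- community_block_indices(tau)
  labels <- sample$labels
  lv <- levels(labels)
  needs_bin <- approach %in% c("average_connectivity", "multivariate_binary")
  Wb <- NULL
  if (needs_bin) {
    if (pooled_threshold) {
      nz <- ew$W[ew$W > 0]
      thr <- if (length(unique(nz)) >= 2) otsu_threshold(nz) else 0
      Wb <- otsu_binarize(ew$W, thr)
    } else {
      Wb <- t(apply(ew$W, 1, function(w) {
        nz <- w[w > 0]
        thr <- if (length(unique(nz)) >= 2) otsu_threshold(nz) else 0
        otsu_binarize(w, thr)
      }))
    }
  }
  res <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (!length(b$idx))
      return(data.frame(block = nm, k = b$k, l = b$l, statistic = NA_real_,
                        p_raw = NA_real_, skipped = TRUE))
    skipped <- FALSE
    out <- switch(approach,
      average_connectivity = {
        cnts <- vapply(lv, function(l)
          sum(Wb[labels == l, b$idx, drop = FALSE]), numeric(1))
        tots <- vapply(lv, function(l)
          sum(labels == l) * length(b$idx), numeric(1))
        suppressWarnings(pearson_chi2_proportions(cnts, tots))
      },
      average_edge_weight = {
        v <- rowMeans(ew$W[, b$idx, drop = FALSE])
        r <- dcorr_scan_scalar(matrix(v, ncol = 1), labels, method = method,
                               n_permutations = n_permutations, seed = seed)
        test_outcome(r$statistic, r$p_raw, r$method)
      },
      multivariate_binary = {
        groups <- lapply(lv, function(l) Wb[labels == l, b$idx, drop = FALSE])
        ksample_dcorr(groups, method = method,
                      n_permutations = n_permutations, seed = seed)
      },
      multivariate_weighted = {
        groups <- lapply(lv, function(l) ew$W[labels == l, b$idx, drop = FALSE])
        ksample_dcorr(groups, method = method,
                      n_permutations = n_permutations, seed = seed)
      })
    data.frame(block = nm, k = b$k, l = b$l, statistic = out$statistic,
               p_raw = out$p_raw, skipped = skipped)
  })
  rows <- do.call(rbind, res)
  tested <- rows[!rows$skipped, , drop = FALSE]
  tested$p_adjusted <- adjust_pvalues(tested$p_raw, correction)
  tested <- rank_components(tested)
  if (any(rows$skipped)) {
    sk <- rows[rows$skipped, , drop = FALSE]
    sk$p_adjusted <- NA_real_
    sk$rank <- nrow(tested) + seq_len(nrow(sk))
    tested <- rbind(tested, sk[, names(tested)])
  }
  new_scan_report(tested, "community", alpha, correction, n_tests = length(blocks))
}

#' Global scan: whole-connectome dissimilarity and 2-D ordination
#'
#' Jointly embeds all graphs, computes the normalized pairwise Frobenius
#' dissimilarity between per-graph embeddings, reduces it to two dimensions
#' with classical MDS, and summarizes the mean within-group and
#' between-group dissimilarity as percentages of the maximum.
#'
#' @param sample a [connectome_sample()] with `m >= 3`.
#' @param d embedding dimension (`NULL` selects from the omnibus scree).
#' @return list with `dissimilarity` (m x m), `coordinates` (m x 2),
#'   `summary` (mean within / between, in percent), `degenerate` flag.
#' @export
global_scan <- function(sample, d = NULL) {
  if (sample$m < 3) stop("global scan needs at least 3 graphs")
  L <- omnibus_embedding(sample$graphs, d = d)
  Draw <- pairwise_embedding_dissimilarity(L, normalize = FALSE)
  # all-identical embeddings leave only numerical noise; do not normalize it
  degenerate <- max(Draw) < sqrt(.Machine$double.eps) * sample$n * L$d
  D <- if (degenerate) Draw * 0 else Draw / max(Draw)
  attr(D, "normalized") <- TRUE
  coords <- if (degenerate) matrix(0, sample$m, 2) else classical_mds(D, 2)
  same <- outer(sample$labels, sample$labels, "==")
  off <- !diag(TRUE, sample$m)
  summary <- c(mean_within = 100 * mean(D[same & off]),
               mean_between = 100 * mean(D[!same]))
  list(dissimilarity = D, coordinates = coords, summary = summary,
       labels = sample$labels, degenerate = degenerate, d = L$d)
}

#' Aggregate a vertex scan across hemispheres
#'
#' For each (left, right) vertex pair, the pair's signal strength is the
#' worse (larger) of the two adjusted p-values, so a pair is only as strong
#' as its weaker hemisphere; pairs are ranked ascending in that value.
#'
#' @param report a vertex-scale `scan_report`.
#' @param pairs 2-column matrix of (left, right) vertex indices; no vertex
#'   may appear twice.
#' @return data.frame of pairs with `p_pair` and `rank`.
#' @export
bilateral_aggregate <- function(report, pairs) {
  if (attr(report, "scale") != "vertex") stop("a vertex-scale report is required")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs needs two columns")
  if (anyDuplicated(as.vector(pairs))) stop("a vertex appears in multiple pairs")
  padj <- setNames(report$p_adjusted, report$vertex)
  left <- padj[as.character(pairs[, 1])]
  right <- padj[as.character(pairs[, 2])]
  if (any(is.na(left)) || any(is.na(right)))
    stop("pairing refers to vertices absent from the report")
  out <- data.frame(left = pairs[, 1], right = pairs[, 2],
                    p_left = unname(left), p_right = unname(right),
                    p_pair = pmax(unname(left), unname(right)))
  ord <- order(out$p_pair, pmin(out$p_left, out$p_right), out$left,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Anatomical confounding scan
#'
#' For each vertex and each single anatomical feature, tests whether the
#' phenotype label and the vertex's joint-embedding latent position are
#' conditionally independent given that feature, using the
#' local-permutation conditional Dcorr test. Cells are Holm-corrected
#' jointly; a cell that fails to reject is flagged as a confounding feature
#' for that vertex (the feature already explains the label signal).
#'
#' @param sample a [connectome_sample()].
#' @param features `m x n x f` array of per-graph, per-vertex anatomical
#'   features (e.g. volume, ADC, FA, RD).
#' @param embedding optional precomputed `latent_positions`; computed from
#'   the sample otherwise.
#' @param d embedding dimension when computing the embedding.
#' @param alpha significance level.
#' @param correction see [adjust_pvalues()].
#' @param n_permutations,n_neighbors,seed conditional test options.
#' @return list with `p_adjusted` (n x f matrix), `confounded` (logical
#'   n x f), and `n_confounders` (per-vertex count).
#' @export
anatomical_confounding_scan <- function(sample, features, embedding = NULL,
                                        d = NULL, alpha = 0.05,
                                        correction = "holm",
                                        n_permutations = 500,
                                        n_neighbors = 10, seed = NULL) {
  if (length(dim(features)) != 3) stop("features must be an m x n x f array")
  if (dim(features)[1] != sample$m || dim(features)[2] != sample$n)
    stop("feature dimensions do not match the sample")
  if (any(!is.finite(features))) stop("features contain missing values")
  if (is.null(embedding)) embedding <- omnibus_embedding(sample$graphs, d = d)
  n <- sample$n
  f <- dim(features)[3]
  praw <- matrix(NA_real_, n, f)
  for (v in seq_len(n)) {
    Xi <- t(vapply(embedding$positions, function(P) P[v, ],
                   numeric(embedding$d)))
    for (q in seq_len(f)) {
      sd_q <- derive_seed(if (is.null(seed)) 0 else seed, v, q)
      out <- conditional_independence_test(sample$labels, Xi,
                                           features[, v, q, drop = TRUE],
                                           n_permutations = n_permutations,
                                           n_neighbors = n_neighbors,
                                           seed = sd_q)
      praw[v, q] <- out$p_raw
    }
  }
  padj <- matrix(adjust_pvalues(as.vector(praw), correction), n, f)
  dimnames(padj) <- dimnames(praw) <- list(NULL, dimnames(features)[[3]])
  confounded <- padj > alpha
  list(p_raw = praw, p_adjusted = padj, confounded = confounded,
       n_confounders = rowSums(confounded))
}
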