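# ---- truncated normal helpers (support [lower, Inf)) --------------------

#' Sample from a normal distribution truncated below
#'
#' Inverse-CDF sampler for a normal distribution restricted to
#' `[lower, Inf)`. Used by the weighted independent-edge and weighted SBM
#' samplers, whose edge weights are nonnegative.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the underlying (untruncated) normal.
#' @param lower truncation point (default 0).
#' @return numeric vector of `n` draws, all `>= lower`.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = 0) {
  if (any(sd <= 0)) stop("sd must be positive")
  plo <- pnorm(lower, mean, sd)
  qnorm(plo + runif(n) * (1 - plo), mean, sd)
}

#' Mean of a normal distribution truncated below
#'
#' Closed form: `mean + sd * dnorm(a) / (1 - pnorm(a))` with
#' `a = (lower - mean) / sd`.
#'
#' @inheritParams rtnorm
#' @return the mean of the truncated distribution.
#' @export
tnorm_mean <- function(mean = 0, sd = 1, lower = 0) {
  a <- (lower - mean) / sd
  tail <- pnorm(a, lower.tail = FALSE)
  # Mills ratio, switching to the asymptotic expansion when the upper tail
  # underflows (deeply truncated case)
  mills <- ifelse(tail > 1e-300, dnorm(a) / tail, a + 1 / a)
  mean + sd * mills
}

# Solve for the underlying normal mean so that the truncated mean equals
# `target` at the given sd. Keeps group means exactly equal in variance-only
# simulation settings despite the nonlinearity introduced by truncation.
tnorm_match_mean <- function(target, sd = 1, lower = 0) {
  f <- function(mu) tnorm_mean(mu, sd, lower) - target
  uniroot(f, lower = target - 10 * sd, upper = target + sd, extendInt = "yes",
          tol = 1e-10)$root
}

# ---- adjacency & sample containers --------------------------------------

#' Validate a weighted adjacency matrix
#'
#' Checks the invariants of a connectome adjacency: square, finite,
#' nonnegative, zero diagonal, and (optionally) exactly symmetric.
#'
#' @param A numeric matrix.
#' @param symmetric logical; require `A == t(A)`.
#' @return `A`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_adjacency <- function(A, symmetric = TRUE) {
  if (!is.matrix(A) || !is.numeric(A)) stop("adjacency must be a numeric matrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(!is.finite(A))) stop("adjacency contains non-finite entries")
  if (any(A < 0)) stop("adjacency contains negative weights")
  if (any(diag(A) != 0)) stop("adjacency has nonzero diagonal (self-loops)")
  if (symmetric && !isTRUE(all.equal(A, t(A), tolerance = 0)) && any(A != t(A)))
    stop("adjacency is not symmetric")
  invisible(A)
}

#' Assemble a labeled sample of connectomes
#'
#' Bundles `m` adjacency matrices on a common vertex set with a categorical
#' phenotype label per graph, plus optional community assignments and
#' hemisphere pairings. Graphs are stored as an `n x n x m` array.
#'
#' @param graphs list of `n x n` matrices, or an `n x n x m` array.
#' @param labels length-`m` vector (coerced to factor) of phenotype labels.
#' @param communities optional length-`n` integer vector of community ids in
#'   `1..K`.
#' @param hemisphere_pairs optional 2-column matrix of (left, right) vertex
#'   indices; no vertex may appear twice.
#' @param symmetric logical; whether the graphs are undirected.
#' @param validate logical; run per-graph invariant checks (disable for large
#'   simulated inputs already known valid).
#' @return an object of class `connectome_sample`.
#' @export
connectome_sample <- function(graphs, labels, communities = NULL,
                              hemisphere_pairs = NULL, symmetric = TRUE,
                              validate = TRUE) {
  if (is.list(graphs)) {
    n <- nrow(graphs[[1]])
    arr <- array(0, c(n, n, length(graphs)))
    for (i in seq_along(graphs)) {
      if (!all(dim(graphs[[i]]) == c(n, n)))
        stop("all graphs must share the same vertex count")
      arr[, , i] <- graphs[[i]]
    }
    graphs <- arr
  }
  stopifnot(length(dim(graphs)) == 3, dim(graphs)[1] == dim(graphs)[2])
  m <- dim(graphs)[3]
  n <- dim(graphs)[1]
  labels <- factor(labels)
  if (length(labels) != m) stop("one label per graph is required")
  if (nlevels(labels) < 2) stop("at least two phenotype classes are required")
  if (validate) for (i in seq_len(m)) validate_adjacency(graphs[, , i], symmetric)
  if (!is.null(communities)) {
    communities <- as.integer(communities)
    if (length(communities) != n) stop("community assignment must cover all vertices")
    if (any(is.na(communities)) || any(communities < 1))
      stop("community ids must be positive integers")
  }
  if (!is.null(hemisphere_pairs)) {
    hemisphere_pairs <- as.matrix(hemisphere_pairs)
    if (ncol(hemisphere_pairs) != 2) stop("hemisphere pairs need two columns")
    if (anyDuplicated(as.vector(hemisphere_pairs)))
      stop("a vertex appears in more than one hemisphere pair")
  }
  structure(list(graphs = graphs, labels = labels, n = n, m = m,
                 communities = communities,
                 hemisphere_pairs = hemisphere_pairs,
                 symmetric = symmetric),
            class = "connectome_sample")
}

#' @export
print.connectome_sample <- function(x, ...) {
  cat("connectome_sample:", x$m, "graphs on", x$n, "vertices;",
      if (x$symmetric) "undirected" else "directed", "\n")
  print(table(x$labels))
  if (!is.null(x$communities))
    cat("communities: K =", max(x$communities), "\n")
  invisible(x)
}

# group sizes guard used by every k-sample test entry point
check_group_sizes <- function(labels, min_per_group = 2) {
  tab <- table(labels)
  if (any(tab < min_per_group))
    stop("every phenotype class needs at least ", min_per_group, " graphs")
  invisible(tab)
}

# ---- model parameter constructors ---------------------------------------

#' Independent-edge model parameters
#'
#' Describes a weighted independent-edge model in which every edge weight is
#' drawn from an edge-specific univariate distribution, all from one family.
#'
#' @param family one of `"truncnorm"` (normal truncated at 0),
#'   `"bernoulli"`, or `"point"` (degenerate point mass).
#' @param mean `n x n` matrix (or scalar, with `n` given) of the family's
#'   location parameter: underlying normal mean, success probability, or the
#'   point-mass value.
#' @param sd matrix/scalar of standard deviations (truncnorm only).
#' @param n vertex count when `mean` is scalar.
#' @param symmetric logical.
#' @return an object of class `ie_model`.
#' @export
ie_model <- function(family = c("truncnorm", "bernoulli", "point"),
                     mean, sd = NULL, n = NULL, symmetric = TRUE) {
  family <- match.arg(family)
  if (!is.matrix(mean)) {
    if (is.null(n)) stop("supply n when mean is scalar")
    mean <- matrix(mean, n, n)
  }
  n <- nrow(mean)
  if (family == "truncnorm") {
    if (is.null(sd)) stop("truncnorm family needs sd")
    if (!is.matrix(sd)) sd <- matrix(sd, n, n)
    if (any(sd <= 0)) stop("sd must be positive")
  }
  if (family == "bernoulli" && (any(mean < 0) || any(mean > 1)))
    stop("bernoulli probabilities must lie in [0,1]")
  if (symmetric) {
    if (any(mean != t(mean))) stop("symmetric model needs a symmetric parameter grid")
    if (!is.null(sd) && any(sd != t(sd))) stop("symmetric model needs symmetric sd grid")
  }
  structure(list(family = family, mean = mean, sd = sd, n = n,
                 symmetric = symmetric), class = "ie_model")
}

#' Sample one graph from an independent-edge model
#'
#' Each upper-triangle entry is drawn independently from its edge-specific
#' distribution; for symmetric models the lower triangle mirrors it. The
#' diagonal is zero.
#'
#' @param params an [ie_model()].
#' @param seed optional integer seed.
#' @return an `n x n` weighted adjacency matrix.
#' @export
sample_ie <- function(params, seed = NULL) {
  stopifnot(inherits(params, "ie_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  k <- sum(ut)
  mu <- params$mean[ut]
  vals <- switch(params$family,
    truncnorm = rtnorm(k, mu, params$sd[ut]),
    bernoulli = rbinom(k, 1, mu),
    point = mu,
    stop("unsupported distribution family"))
  A[ut] <- vals
  if (params$symmetric) {
    A <- A + t(A)
  } else {
    lt <- lower.tri(A)
    mu2 <- params$mean[lt]
    A[lt] <- switch(params$family,
      truncnorm = rtnorm(k, mu2, params$sd[lt]),
      bernoulli = rbinom(k, 1, mu2),
      point = mu2)
  }
  A
}

#' Sample a random dot product graph
#'
#' Draws a binary symmetric adjacency with edge `(i,j)` present with
#' probability `x_i . x_j`, the dot product of the incident latent positions.
#'
#' @param X `n x d` matrix of latent positions; all pairwise dot products
#'   must lie in `[0, 1]`.
#' @param seed optional integer seed.
#' @return an `n x n` binary adjacency matrix with zero diagonal.
#' @export
sample_rdpg <- function(X, seed = NULL) {
  X <- as.matrix(X)
  P <- tcrossprod(X)
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("latent positions give edge probabilities outside [0,1]")
  P <- pmin(pmax(P, 0), 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(P)
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- rbinom(sum(ut), 1, P[ut])
  A + t(A)
}

#' Stochastic block model parameters
#'
#' @param B `K x K` matrix of block connection probabilities, or (weighted
#'   variant) leave `B = NULL` and give `mean`/`sd` matrices of
#'   truncated-normal block parameters.
#' @param mean,sd optional `K x K` matrices for the weighted (truncated
#'   normal) variant.
#' @param symmetric logical.
#' @return an object of class `sbm_model`.
#' @export
sbm_model <- function(B = NULL, mean = NULL, sd = NULL, symmetric = TRUE) {
  if (is.null(B) == is.null(mean))
    stop("give exactly one of B (binary) or mean/sd (weighted)")
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (any(B < 0) || any(B > 1)) stop("block probabilities must lie in [0,1]")
    if (symmetric && any(B != t(B))) stop("B must be symmetric for undirected graphs")
    K <- nrow(B)
    weighted <- FALSE
  } else {
    mean <- as.matrix(mean); sd <- as.matrix(sd)
    stopifnot(all(dim(mean) == dim(sd)))
    K <- nrow(mean)
    weighted <- TRUE
  }
  structure(list(B = B, mean = mean, sd = sd, K = K, weighted = weighted,
                 symmetric = symmetric), class = "sbm_model")
}

#' Sample a stochastic block model graph
#'
#' Binary variant: edge `(i,j)` is Bernoulli with probability
#' `B[tau_i, tau_j]`. Weighted variant: the edge weight is drawn from the
#' block's truncated-normal distribution (a block whose mean and sd are both
#' zero stays empty).
#'
#' @param params an [sbm_model()].
#' @param tau length-`n` integer community assignment in `1..K`.
#' @param seed optional integer seed.
#' @return an `n x n` adjacency matrix.
#' @export
sample_sbm <- function(params, tau, seed = NULL) {
  stopifnot(inherits(params, "sbm_model"))
  tau <- as.integer(tau)
  if (any(tau < 1) || any(tau > params$K))
    stop("community assignment entries must lie in 1..K")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tau)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  bi <- tau[row(A)[ut]]
  bj <- tau[col(A)[ut]]
  if (!params$weighted) {
    p <- params$B[cbind(bi, bj)]
    A[ut] <- rbinom(length(ut), 1, p)
  } else {
    mu <- params$mean[cbind(bi, bj)]
    s <- params$sd[cbind(bi, bj)]
    w <- numeric(length(ut))
    live <- s > 0
    w[live] <- rtnorm(sum(live), mu[live], s[live])
    w[!live] <- mu[!live]
    A[ut] <- w
  }
  A + t(A)
}

# ---- deterministic per-replicate seed streams ---------------------------

#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus index coordinates (replicate,
#' setting, ...) to a 31-bit child seed, so any replicate of a benchmark can
#' be reproduced in isolation.
#'
#' @param seed master seed (integer).
#' @param ... one or more nonnegative integer indices.
#' @return an integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (v in idx) h <- (h * 48271 + as.numeric(v) + 1) %% 2147483647
  as.integer(h)
}

# ---- simulation generators ----------------------------------------------

#' Configuration for the edge-scale simulation
#'
#' Two populations of weighted independent-edge graphs. Null edges are
#' i.i.d. from a baseline normal truncated at zero in both groups; in group
#' 2 the signal edges have their realized mean shifted by `delta` and their
#' underlying standard deviation scaled by `1 + phi`.
#'
#' @param n_vertices vertex count.
#' @param n_per_group graphs per group (N).
#' @param delta mean shift of signal edges (same units as edge weights).
#' @param phi relative increase of the signal-edge standard deviation.
#' @param n_signal number of planted signal edges.
#' @param base_mean,base_sd baseline underlying normal parameters
#'   (truncation at 0).
#' @param seed master seed.
#' @return a `edge_sim_config` list.
#' @export
edge_sim_config <- function(n_vertices = 20, n_per_group = 20, delta = 1,
                            phi = 0, n_signal = 10, base_mean = 10,
                            base_sd = 1, seed = 1) {
  stopifnot(n_per_group >= 2, delta >= 0, phi >= 0)
  n_edges <- n_vertices * (n_vertices - 1) / 2
  if (n_signal > n_edges) stop("n_signal exceeds the number of edges")
  structure(list(n_vertices = n_vertices, n_per_group = n_per_group,
                 delta = delta, phi = phi, n_signal = n_signal,
                 base_mean = base_mean, base_sd = base_sd, seed = seed),
            class = "edge_sim_config")
}

#' Generate an edge-scale two-population sample with planted signal edges
#'
#' @param config an [edge_sim_config()].
#' @return list with `sample` (a [connectome_sample()]) and `truth`
#'   (2-column matrix of signal-edge endpoints, i < j).
#' @export
generate_edge_sim <- function(config) {
  stopifnot(inherits(config, "edge_sim_config"))
  set.seed(config$seed)
  n <- config$n_vertices
  N <- config$n_per_group
  base_m <- matrix(config$base_mean, n, n)
  base_s <- matrix(config$base_sd, n, n)
  ut <- which(upper.tri(base_m))
  signal_idx <- sort(sample(ut, config$n_signal))
  # group 2: shift the realized (truncated) mean by delta, scale sd by 1+phi
  sd2 <- config$base_sd * (1 + config$phi)
  target <- tnorm_mean(config$base_mean, config$base_sd) + config$delta
  mu2 <- tnorm_match_mean(target, sd2)
  sym <- function(M, idx, val) { M[idx] <- val; M[lower.tri(M)] <- t(M)[lower.tri(M)]; M }
  m2 <- sym(base_m, signal_idx, mu2)
  s2 <- sym(base_s, signal_idx, sd2)
  mod1 <- ie_model("truncnorm", mean = base_m, sd = base_s)
  mod2 <- ie_model("truncnorm", mean = m2, sd = s2)
  graphs <- array(0, c(n, n, 2 * N))
  for (i in seq_len(N)) graphs[, , i] <- sample_ie(mod1)
  for (i in seq_len(N)) graphs[, , N + i] <- sample_ie(mod2)
  labels <- rep(c("g1", "g2"), each = N)
  truth <- cbind(row(base_m)[signal_idx], col(base_m)[signal_idx])
  colnames(truth) <- c("i", "j")
  list(sample = connectome_sample(graphs, labels, validate = FALSE),
       truth = truth)
}

#' Configuration for the vertex-scale simulation
#'
#' Two populations of 50-vertex RDPG draws. Group 1 uses a common base
#' latent position for every vertex; in group 2 the planted signal vertices
#' have their latent position stretched by a constant (and, for
#' `rotate_and_stretch`, first rotated in the plane).
#'
#' Defaults (base position, stretch, rotation, per-group size) are the
#' package's calibrated simulation conditions; see the methods vignette.
#'
#' @param n_vertices vertex count (50 in the reference setting).
#' @param n_per_group graphs per group.
#' @param n_signal number of planted signal vertices.
#' @param kind `"stretch"` or `"rotate_and_stretch"`.
#' @param base latent position shared by all vertices (length-2).
#' @param stretch multiplicative stretch applied to signal positions.
#' @param angle planar rotation (radians) applied before stretching in the
#'   `rotate_and_stretch` setting.
#' @param seed master seed.
#' @return a `vertex_sim_config` list.
#' @export
vertex_sim_config <- function(n_vertices = 50, n_per_group = 8, n_signal = 10,
                              kind = c("stretch", "rotate_and_stretch"),
                              base = c(0.45, 0.45), stretch = NULL,
                              angle = acos(1 / 1.3), seed = 1) {
  kind <- match.arg(kind)
  if (is.null(stretch)) stretch <- if (kind == "stretch") 1.19 else 1.3
  stopifnot(n_per_group >= 2, n_signal >= 1, n_signal <= n_vertices)
  structure(list(n_vertices = n_vertices, n_per_group = n_per_group,
                 n_signal = n_signal, kind = kind, base = base,
                 stretch = stretch, angle = angle, seed = seed),
            class = "vertex_sim_config")
}

#' Generate a vertex-scale two-population sample with planted signal vertices
#'
#' @param config a [vertex_sim_config()].
#' @return list with `sample`, `truth` (signal vertex indices), and the two
#'   latent position matrices `X1`, `X2`.
#' @export
generate_vertex_sim <- function(config) {
  stopifnot(inherits(config, "vertex_sim_config"))
  set.seed(config$seed)
  n <- config$n_vertices
  N <- config$n_per_group
  X1 <- matrix(rep(config$base, each = n), n, 2)
  truth <- sort(sample.int(n, config$n_signal))
  v <- config$base
  if (config$kind == "rotate_and_stretch") {
    th <- config$angle
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    v <- as.vector(R %*% v)
  }
  v <- config$stretch * v
  X2 <- X1
  X2[truth, ] <- matrix(rep(v, each = length(truth)), length(truth), 2)
  for (X in list(X1, X2)) {
    P <- tcrossprod(X)
    if (any(P > 1) || any(P < 0))
      stop("perturbation pushes edge probabilities outside [0,1]")
  }
  graphs <- array(0, c(n, n, 2 * N))
  for (i in seq_len(N)) graphs[, , i] <- sample_rdpg(X1)
  for (i in seq_len(N)) graphs[, , N + i] <- sample_rdpg(X2)
  labels <- rep(c("g1", "g2"), each = N)
  list(sample = connectome_sample(graphs, labels, validate = FALSE),
       truth = truth, X1 = X1, X2 = X2)
}

#' Configuration for the community-scale simulation
#'
#' Two populations of weighted SBM draws with a 3-community block-diagonal
#' structure. Block 1 is null (identical weight distributions in the two
#' groups); block 2 has equal means but different variances; block 3 has
#' different means. Off-diagonal blocks carry no edges.
#'
#' @param n_per_community vertices in each of the 3 communities.
#' @param n_per_group graphs per group (N).
#' @param base_mean,base_sd baseline truncated-normal parameters for all
#'   blocks in group 1.
#' @param var_ratio multiplicative sd inflation of block 2 in group 2
#'   (means matched exactly).
#' @param delta realized-mean shift of block 3 in group 2.
#' @param null_all if TRUE, make all three blocks null (for false-positive
#'   calibration).
#' @param seed master seed.
#' @return a `community_sim_config` list.
#' @export
community_sim_config <- function(n_per_community = 10, n_per_group = 30,
                                 base_mean = 1, base_sd = 0.5,
                                 var_ratio = 1.6, delta = 0.15,
                                 null_all = FALSE, seed = 1) {
  stopifnot(n_per_group >= 2, var_ratio > 0, delta >= 0)
  structure(list(n_per_community = n_per_community, n_per_group = n_per_group,
                 base_mean = base_mean, base_sd = base_sd,
                 var_ratio = var_ratio, delta = delta, null_all = null_all,
                 seed = seed),
            class = "community_sim_config")
}

#' Generate a community-scale two-population sample with planted signal blocks
#'
#' @param config a [community_sim_config()].
#' @return list with `sample` (communities attached), `truth` (signal
#'   diagonal-block indices; empty when `null_all`), and `tau`.
#' @export
generate_community_sim <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  set.seed(config$seed)
  K <- 3
  nc <- config$n_per_community
  n <- K * nc
  N <- config$n_per_group
  tau <- rep(seq_len(K), each = nc)
  mk <- function(diag_mean, diag_sd) {
    mean <- matrix(0, K, K); sd <- matrix(0, K, K)
    diag(mean) <- diag_mean; diag(sd) <- diag_sd
    sbm_model(mean = mean, sd = sd)
  }
  mu0 <- config$base_mean; s0 <- config$base_sd
  mod1 <- mk(rep(mu0, K), rep(s0, K))
  if (config$null_all) {
    mod2 <- mod1
    truth <- integer(0)
  } else {
    sd2 <- s0 * config$var_ratio
    mu_var <- tnorm_match_mean(tnorm_mean(mu0, s0), sd2)   # block 2: equal mean
    mu_shift <- tnorm_match_mean(tnorm_mean(mu0, s0) + config$delta, s0) # block 3
    mod2 <- mk(c(mu0, mu_var, mu_shift), c(s0, sd2, s0))
    truth <- c(2L, 3L)
  }
  graphs <- array(0, c(n, n, 2 * N))
  for (i in seq_len(N)) graphs[, , i] <- sample_sbm(mod1, tau)
  for (i in seq_len(N)) graphs[, , N + i] <- sample_sbm(mod2, tau)
  labels <- rep(c("g1", "g2"), each = N)
  list(sample = connectome_sample(graphs, labels, communities = tau,
                                  validate = FALSE),
       truth = truth, tau = tau)
}
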