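# shared fixture builders for the test suite

# small two-group sample of weighted IE graphs (optionally with a planted
# mean-shifted edge set)
make_ie_sample <- function(n = 8, N = 6, delta = 0, seed = 1) {
  sim <- generate_edge_sim(edge_sim_config(n_vertices = n, n_per_group = N,
                                           delta = delta, phi = 0,
                                           n_signal = min(3, n), seed = seed))
  sim
}

# two-group RDPG sample from a common latent position matrix (global null)
make_null_rdpg_sample <- function(n = 30, N = 6, seed = 1, d2 = 0.45) {
  set.seed(seed)
  X <- matrix(d2, n, 2)
  graphs <- array(0, c(n, n, 2 * N))
  for (i in seq_len(2 * N)) graphs[, , i] <- sample_rdpg(X)
  connectome_sample(graphs, rep(c("a", "b"), each = N), validate = FALSE)
}

# random symmetric weighted adjacency with zero diagonal
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# brute-force unbiased dcorr used as an independent oracle (naive loops,
# straight from the U-centering definition)
oracle_udcorr <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- sqrt(2) * outer(y, y, "!=")
  uc <- function(D) {
    U <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      U[i, j] <- D[i, j] - sum(D[i, -i]) / (n - 2) - sum(D[-j, j]) / (n - 2) +
        sum(D) / ((n - 1) * (n - 2))
    }
    U
  }
  Ua <- uc(a); Ub <- uc(b)
  sum(Ua * Ub) / sqrt(sum(Ua^2) * sum(Ub^2))
}
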