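# Spectral representations: adjacency spectral embedding, omnibus joint
# embedding, scree-based dimension selection, classical MDS, and pairwise
# embedding dissimilarities.

# canonicalize per-dimension sign: largest-magnitude loading made positive
canonicalize_signs <- function(X) {
  for (j in seq_len(ncol(X))) {
    i <- which.max(abs(X[, j]))
    if (length(i) && X[i, j] < 0) X[, j] <- -X[, j]
  }
  X
}

#' Adjacency spectral embedding
#'
#' Embeds a (possibly weighted) symmetric adjacency matrix into `d`
#' dimensions via the top-`d` eigenpairs by magnitude: rows are
#' `U_d |S_d|^{1/2}`. Per-dimension signs are canonicalized (the
#' largest-magnitude loading in each dimension is made positive) so the
#' output is deterministic.
#'
#' @param A symmetric numeric matrix.
#' @param d embedding dimension, `1 <= d <= n`.
#' @return `n x d` matrix of estimated latent positions.
#' @export
adjacency_spectral_embedding <- function(A, d) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (d < 1 || d > n) stop("embedding dimension must satisfy 1 <= d <= n")
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(d)]
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  X <- vecs %*% diag(sqrt(abs(vals)), d, d)
  canonicalize_signs(X)
}

#' Build the omnibus matrix of a graph collection
#'
#' The `(mn) x (mn)` block matrix whose diagonal blocks are the `A_i` and
#' whose off-diagonal `(i, j)` block is `(A_i + A_j) / 2`.
#'
#' @param graphs list of `n x n` matrices or an `n x n x m` array.
#' @return the omnibus matrix.
#' @export
build_omnibus_matrix <- function(graphs) {
  if (is.list(graphs)) {
    n <- nrow(graphs[[1]])
    if (!all(vapply(graphs, function(g) all(dim(g) == c(n, n)), logical(1))))
      stop("all graphs must share the same vertex count")
    arr <- array(unlist(graphs), c(n, n, length(graphs)))
  } else arr <- graphs
  stopifnot(length(dim(arr)) == 3)
  n <- dim(arr)[1]
  if (dim(arr)[2] != n) stop("graphs must be square")
  m <- dim(arr)[3]
  M <- matrix(0, m * n, m * n)
  for (i in seq_len(m)) {
    ri <- ((i - 1) * n + 1):(i * n)
    for (j in i:m) {
      rj <- ((j - 1) * n + 1):(j * n)
      blk <- (arr[, , i] + arr[, , j]) / 2
      M[ri, rj] <- blk
      if (j > i) M[rj, ri] <- t(blk)
    }
  }
  M
}

#' Omnibus embedding of a graph collection
#'
#' Jointly embeds `m` graphs on a common vertex set by applying the
#' adjacency spectral embedding to the omnibus matrix and splitting the
#' result into `m` consecutive `n x d` blocks (one per graph, in input
#' order). The blocks live in a common Euclidean space, so per-vertex latent
#' positions can be compared across graphs without further alignment.
#'
#' @param graphs list of matrices or an `n x n x m` array.
#' @param d embedding dimension (`1 <= d <= mn`); if `NULL`, selected from
#'   the omnibus scree via [select_embedding_dimension()].
#' @return object of class `latent_positions`: list with `positions` (list
#'   of m `n x d` matrices), `d`, `n`, `m`.
#' @export
omnibus_embedding <- function(graphs, d = NULL) {
  M <- build_omnibus_matrix(graphs)
  n <- if (is.list(graphs)) nrow(graphs[[1]]) else dim(graphs)[1]
  m <- nrow(M) / n
  if (is.null(d)) d <- select_embedding_dimension(M)
  if (d > nrow(M)) stop("embedding dimension exceeds mn")
  X <- adjacency_spectral_embedding(M, d)
  positions <- lapply(seq_len(m), function(i)
    X[((i - 1) * n + 1):(i * n), , drop = FALSE])
  structure(list(positions = positions, d = d, n = n, m = m),
            class = "latent_positions")
}

#' @export
print.latent_positions <- function(x, ...) {
  cat("latent_positions:", x$m, "graphs,", x$n, "vertices, d =", x$d, "\n")
  invisible(x)
}

#' Select an embedding dimension from a scree
#'
#' Profile-likelihood elbow selection (Zhu--Ghodsi style): for every split
#' point of the magnitude-sorted spectrum, fit two normal means with a
#' pooled variance and keep the split maximizing the likelihood.
#'
#' @param x a symmetric matrix (its spectrum is used) or a numeric vector of
#'   singular values.
#' @param max_dim consider at most this many leading values.
#' @return the selected dimension (integer).
#' @export
select_embedding_dimension <- function(x, max_dim = NULL) {
  if (is.matrix(x)) x <- abs(eigen(x, symmetric = TRUE, only.values = TRUE)$values)
  s <- sort(abs(as.numeric(x)), decreasing = TRUE)
  if (!is.null(max_dim)) s <- s[seq_len(min(max_dim, length(s)))]
  p <- length(s)
  if (p < 2) stop("need at least 2 singular values")
  if (sd(s) == 0) {
    warning("constant spectrum; returning d = 1")
    return(1L)
  }
  ll <- rep(-Inf, p - 1)
  for (q in seq_len(p - 1)) {
    m1 <- mean(s[1:q]); m2 <- mean(s[(q + 1):p])
    ss <- sum((s[1:q] - m1)^2) + sum((s[(q + 1):p] - m2)^2)
    sig <- sqrt(ss / p)
    if (sig == 0) sig <- .Machine$double.eps
    ll[q] <- sum(dnorm(s[1:q], m1, sig, log = TRUE)) +
      sum(dnorm(s[(q + 1):p], m2, sig, log = TRUE))
  }
  which.max(ll)
}

#' Classical multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, takes the top-`d` eigenpairs with positive
#' eigenvalues, and scales eigenvectors by root eigenvalues. Signs are
#' canonicalized as in [adjacency_spectral_embedding()].
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param d target dimension.
#' @return `m x d` coordinate matrix (fewer columns, with a warning, if
#'   there are fewer than `d` positive eigenvalues).
#' @export
classical_mds <- function(D, d = 2) {
  D <- as.matrix(D)
  m <- nrow(D)
  stopifnot(ncol(D) == m)
  if (any(abs(diag(D)) > 1e-12)) stop("dissimilarity matrix must have zero diagonal")
  J <- diag(m) - matrix(1 / m, m, m)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  if (length(pos) < d) {
    warning("fewer positive eigenvalues than requested dimensions; truncating")
    d <- max(length(pos), 1L)
  }
  keep <- pos[seq_len(min(d, length(pos)))]
  if (!length(keep)) return(matrix(0, m, 1))
  X <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep), length(keep))
  canonicalize_signs(X)
}

#' Pairwise Frobenius dissimilarity between jointly embedded graphs
#'
#' Entry `(i, j)` is the Frobenius norm of the difference between the
#' embeddings of graphs `i` and `j`; optionally standardized by the largest
#' pairwise dissimilarity so the maximum entry is 1.
#'
#' @param L a `latent_positions` object from [omnibus_embedding()].
#' @param normalize divide by the maximum entry.
#' @return `m x m` symmetric dissimilarity matrix with zero diagonal.
#' @export
pairwise_embedding_dissimilarity <- function(L, normalize = TRUE) {
  stopifnot(inherits(L, "latent_positions"))
  m <- L$m
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    D[i, j] <- D[j, i] <- sqrt(sum((L$positions[[i]] - L$positions[[j]])^2))
  }
  if (normalize) {
    mx <- max(D)
    if (mx > 0) D <- D / mx
  }
  attr(D, "normalized") <- normalize
  D
}
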