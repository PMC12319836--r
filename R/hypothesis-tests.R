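# Statistical primitives: unbiased k-sample distance correlation (with
# permutation and chi-square null approximations), Hotelling's T-squared,
# one-way MANOVA via Pillai's trace, Pearson chi-squared on proportions,
# Otsu thresholding, a local-permutation conditional independence test, and
# multiplicity corrections.

#' Construct a test outcome record
#'
#' @param statistic test statistic.
#' @param p_raw raw p-value.
#' @param method character tag.
#' @param df optional degrees of freedom (length-2 numeric).
#' @param n_permutations optional permutation count.
#' @param p_adjusted adjusted p-value (NA until a correction is applied).
#' @return object of class `test_outcome`.
#' @export
test_outcome <- function(statistic, p_raw, method, df = NULL,
                         n_permutations = NULL, p_adjusted = NA_real_) {
  stopifnot(p_raw >= 0, p_raw <= 1)
  structure(list(statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, df = df, method = method,
                 n_permutations = n_permutations),
            class = "test_outcome")
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$method, x$statistic, x$p_raw))
  if (!is.null(x$df)) cat(sprintf(", df = (%g, %g)", x$df[1], x$df[2]))
  cat("\n")
  invisible(x)
}

# ---- unbiased distance correlation core ---------------------------------

# U-centering of a distance matrix (unbiased variant); diagonal zeroed.
ucenter <- function(D) {
  n <- nrow(D)
  if (n < 4) stop("U-centering requires at least 4 observations")
  R <- rowSums(D)
  Tt <- sum(R)
  U <- D - outer(R, rep(1 / (n - 2), n)) - outer(rep(1 / (n - 2), n), colSums(D)) +
    Tt / ((n - 1) * (n - 2))
  diag(U) <- 0
  U
}

# one-hot label distance matrix: 0 within class, sqrt(2) between
label_distance <- function(labels) {
  labels <- as.integer(factor(labels))
  D <- sqrt(2) * (outer(labels, labels, "!=") * 1)
  diag(D) <- 0
  D
}

# unbiased dcorr between two U-centered matrices
udcorr_stat <- function(Ux, Uy) {
  vx <- sum(Ux * Ux); vy <- sum(Uy * Uy)
  if (vx <= 0 || vy <= 0) return(0)
  sum(Ux * Uy) / sqrt(vx * vy)
}

# chi-square upper-tail approximation of the unbiased Dcorr null:
# n * stat + 1 is compared to a chi-square(1) reference
dcorr_chisq_p <- function(stat, n) {
  pchisq(pmax(n * stat + 1, 0), df = 1, lower.tail = FALSE)
}

#' k-sample distance correlation test
#'
#' Tests equality in distribution of `k >= 2` groups of (possibly
#' multivariate) observations by reformulating the k-sample problem as an
#' independence test: observations are stacked, a Euclidean distance matrix
#' is paired with a one-hot label distance matrix, and the unbiased
#' (U-centered) distance correlation between the two is the test statistic.
#' The null is calibrated either by label permutation (add-one estimator) or
#' by a chi-square approximation of the unbiased statistic's null
#' distribution (valid for total sample sizes of roughly 20 and above).
#'
#' @param groups list of `k` matrices (observations x features) or numeric
#'   vectors (scalar features).
#' @param method `"auto"` (chi-square when total n >= 20, else permutation),
#'   `"permutation"`, or `"chi_square"`.
#' @param n_permutations permutation count (permutation method).
#' @param seed optional seed for the permutation draw.
#' @return a [test_outcome()].
#' @export
ksample_dcorr <- function(groups, method = c("auto", "permutation", "chi_square"),
                          n_permutations = 1000, seed = NULL) {
  method <- match.arg(method)
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  sizes <- vapply(groups, nrow, integer(1))
  if (length(groups) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  n <- sum(sizes)
  if (method == "auto") method <- if (n >= 20) "chi_square" else "permutation"
  if (method == "chi_square" && n < 20)
    warning("chi-square approximation requested with total n < 20; ",
            "the approximation may be invalid at this sample size")
  X <- do.call(rbind, groups)
  labels <- rep(seq_along(groups), sizes)
  Dx <- as.matrix(dist(X))
  Ux <- ucenter(Dx)
  Uy <- ucenter(label_distance(labels))
  stat <- udcorr_stat(Ux, Uy)
  if (method == "chi_square") {
    p <- dcorr_chisq_p(stat, n)
    return(test_outcome(stat, p, "ksample_dcorr_chisq"))
  }
  if (!is.null(seed)) set.seed(seed)
  vy <- sum(Uy * Uy)
  cnt <- 0L
  for (b in seq_len(n_permutations)) {
    pidx <- sample.int(n)
    sp <- udcorr_stat(Ux[pidx, pidx], Uy)
    if (sp >= stat - 1e-12) cnt <- cnt + 1L
  }
  p <- (1 + cnt) / (n_permutations + 1)
  test_outcome(stat, p, "ksample_dcorr_perm", n_permutations = n_permutations)
}

# ---- vectorized scalar Dcorr scan engine --------------------------------
# Runs the k-sample Dcorr test simultaneously for every column of a
# subjects-by-components weight matrix (one scalar response per component).
# This is what makes full edge scans on hundreds of vertices tractable.
# Returns list(statistic, p_raw, method).
scalar_ucentered <- function(W) {
  W <- as.matrix(W)
  m <- nrow(W)
  ii <- rep(seq_len(m), times = m)
  jj <- rep(seq_len(m), each = m)
  # m^2 x E matrix of pairwise absolute differences, one column per component
  Dmat <- abs(W[ii, , drop = FALSE] - W[jj, , drop = FALSE])
  rs <- rowsum(Dmat, ii)            # m x E row sums of each distance matrix
  tot <- colSums(rs)
  U <- Dmat - rs[ii, , drop = FALSE] / (m - 2) - rs[jj, , drop = FALSE] / (m - 2) +
    rep(tot, each = m * m) / ((m - 1) * (m - 2))
  U[ii == jj, ] <- 0
  list(U = U, vx = colSums(U * U), m = m)
}

dcorr_scan_scalar <- function(W, labels, method = c("auto", "permutation", "chi_square"),
                              n_permutations = 1000, seed = NULL,
                              perm_chunk = 250L) {
  method <- match.arg(method)
  W <- as.matrix(W)
  m <- nrow(W)
  E <- ncol(W)
  if (method == "auto") method <- if (m >= 20) "chi_square" else "permutation"
  sc <- scalar_ucentered(W)
  U <- sc$U
  Uy <- ucenter(label_distance(labels))
  uy <- as.vector(Uy)
  vy <- sum(uy * uy)
  vx <- sc$vx
  denom <- sqrt(vx * vy)
  stat <- as.vector(crossprod(U, uy))
  stat <- ifelse(denom > 0, stat / denom, 0)
  if (method == "chi_square") {
    return(list(statistic = stat, p_raw = dcorr_chisq_p(stat, m),
                method = "ksample_dcorr_chisq"))
  }
  if (!is.null(seed)) set.seed(seed)
  cnt <- numeric(E)
  done <- 0L
  while (done < n_permutations) {
    nb <- min(perm_chunk, n_permutations - done)
    Bp <- matrix(0, m * m, nb)
    for (b in seq_len(nb)) {
      pidx <- sample.int(m)
      Bp[, b] <- as.vector(Uy[pidx, pidx])
    }
    S <- crossprod(U, Bp)                     # E x nb permuted inner products
    S <- S / ifelse(denom > 0, denom, 1)
    cnt <- cnt + rowSums(S >= stat - 1e-12)
    done <- done + nb
  }
  list(statistic = stat, p_raw = (1 + cnt) / (n_permutations + 1),
       method = "ksample_dcorr_perm")
}

# ---- Hotelling / MANOVA -------------------------------------------------

#' Hotelling's T-squared two-sample test
#'
#' `T2 = n1 n2 / (n1 + n2) * (xbar1 - xbar2)' S_pooled^{-1} (xbar1 - xbar2)`
#' with the exact F reference `F = T2 (n1 + n2 - d - 1) / (d (n1 + n2 - 2))`
#' on `(d, n1 + n2 - d - 1)` degrees of freedom. A singular pooled
#' covariance falls back to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param group1,group2 matrices (observations x features) or vectors.
#' @return a [test_outcome()] with `df = c(df1, df2)`.
#' @export
hotelling_t2 <- function(group1, group2) {
  x1 <- as.matrix(group1); x2 <- as.matrix(group2)
  d <- ncol(x1)
  if (ncol(x2) != d) stop("feature dimensions differ")
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  if (d >= n1 + n2 - 1) stop("need d < n1 + n2 - 1")
  diffm <- colMeans(x1) - colMeans(x2)
  Sp <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  sol <- tryCatch(solve(Sp, diffm), error = function(e) NULL)
  if (is.null(sol)) {
    warning("singular pooled covariance; using pseudo-inverse")
    sol <- MASS::ginv(Sp) %*% diffm
  }
  T2 <- as.numeric((n1 * n2 / (n1 + n2)) * crossprod(diffm, sol))
  T2 <- max(T2, 0)
  df1 <- d
  df2 <- n1 + n2 - d - 1
  Fstat <- T2 * df2 / (d * (n1 + n2 - 2))
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  out <- test_outcome(T2, p, "hotelling_t2", df = c(df1, df2))
  out$F <- Fstat
  out
}

#' One-way MANOVA with Pillai's trace
#'
#' Computes Pillai's trace `V = tr(H (H + E)^{-1})` from the between-group
#' (`H`) and within-group (`E`) sums-of-squares-and-cross-products matrices,
#' and its approximate F with s = min(d, k - 1), m = (|d - k + 1| - 1) / 2,
#' r = (N - k - d - 1) / 2:
#' `F = ((2r + s + 1) / (2m + s + 1)) * V / (s - V)` on
#' `(s (2m + s + 1), s (2r + s + 1))` degrees of freedom. At `k = 2` this is
#' exactly Hotelling's T-squared F test.
#'
#' @param groups list of `k >= 2` matrices (observations x features).
#' @return a [test_outcome()] with Pillai's trace as statistic, plus `$F`.
#' @export
manova_pillai <- function(groups) {
  groups <- lapply(groups, as.matrix)
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  d <- ncol(groups[[1]])
  sizes <- vapply(groups, nrow, integer(1))
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  N <- sum(sizes)
  if (N <= k + d) stop("total sample size must exceed k + d")
  X <- do.call(rbind, groups)
  grand <- colMeans(X)
  H <- matrix(0, d, d); E <- matrix(0, d, d)
  for (g in seq_len(k)) {
    mg <- colMeans(groups[[g]])
    H <- H + sizes[g] * tcrossprod(mg - grand)
    C <- sweep(groups[[g]], 2, mg)
    E <- E + crossprod(C)
  }
  HEinv <- tryCatch(solve(H + E), error = function(e) {
    warning("singular H + E; using pseudo-inverse")
    MASS::ginv(H + E)
  })
  V <- sum(diag(H %*% HEinv))
  s <- min(d, k - 1)
  mm <- (abs(d - k + 1) - 1) / 2
  r <- (N - k - d - 1) / 2
  df1 <- s * (2 * mm + s + 1)
  df2 <- s * (2 * r + s + 1)
  Fstat <- ((2 * r + s + 1) / (2 * mm + s + 1)) * V / (s - V)
  if (!is.finite(Fstat)) Fstat <- Inf
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  out <- test_outcome(V, p, "manova_pillai", df = c(df1, df2))
  out$F <- Fstat
  out
}

# ---- Pearson chi-squared on proportions ---------------------------------

#' Pearson chi-squared test for equality of k proportions
#'
#' Tests homogeneity of success probabilities across `k` groups from a
#' `k x 2` table of successes and failures (df = k - 1, asymptotic
#' p-value, no continuity correction).
#'
#' @param successes,totals length-k integer vectors.
#' @return a [test_outcome()].
#' @export
pearson_chi2_proportions <- function(successes, totals) {
  stopifnot(length(successes) == length(totals), all(totals > 0),
            all(successes >= 0), all(successes <= totals))
  tab <- cbind(successes, totals - successes)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 1))
    warning("expected cell count below 1; chi-squared approximation is unreliable")
  if (any(colSums(tab) == 0)) {
    # all successes or all failures: no variation to test
    return(test_outcome(0, 1, "pearson_chi2", df = c(length(totals) - 1, NA)))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  test_outcome(unname(ct$statistic), unname(ct$p.value), "pearson_chi2",
               df = c(unname(ct$parameter), NA))
}

# ---- Otsu threshold -----------------------------------------------------

#' Otsu's threshold for binarizing edge weights
#'
#' Maximizes the between-class variance over a fixed 256-bin histogram of
#' the values; ties are broken toward the lower bin edge. The binarization
#' convention is `weight > threshold -> 1`.
#'
#' @param values nonnegative numeric vector with at least 2 distinct values.
#' @param n_bins histogram resolution (fixed default 256 for
#'   reproducibility).
#' @return the threshold (a bin edge strictly inside the value range).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2)
    stop("Otsu threshold is undefined for fewer than 2 distinct values")
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  total <- w[n_bins]
  csum <- cumsum(counts * mids)
  mu_t <- csum[n_bins] / total
  w0 <- w[-n_bins] / total
  mu0 <- csum[-n_bins] / w[-n_bins]
  valid <- w0 > 0 & w0 < 1
  mu1 <- (csum[n_bins] - csum[-n_bins]) / (total - w[-n_bins])
  bc <- ifelse(valid, w0 * (1 - w0) * (mu0 - mu1)^2, -Inf)
  t_idx <- which.max(bc)  # which.max takes the first (lowest-edge) maximum
  edges[t_idx + 1]
}

# binarize a weight array/matrix with the Otsu convention (> threshold)
otsu_binarize <- function(x, threshold) (x > threshold) * 1

# ---- conditional independence (local permutation Dcorr) -----------------

#' Conditional independence test via locally permuted distance correlation
#'
#' Tests `(Y independent of X) | Z` for a categorical `Y`: the test
#' statistic is the unbiased distance correlation between `X` and the
#' one-hot encoding of `Y`, and the null distribution is generated by
#' permuting labels only among nearest neighbors in `Z`-space (random
#' transpositions along the Z k-nearest-neighbor graph), which preserves the
#' dependence of `Y` on `Z` while breaking any residual dependence on `X`.
#'
#' @param y categorical vector (length n).
#' @param x matrix of features carrying the putative extra signal.
#' @param z matrix of conditioning features (at least 1 column).
#' @param n_permutations local-permutation count.
#' @param n_neighbors neighborhood size for the local permutations.
#' @param seed optional seed.
#' @return a [test_outcome()].
#' @export
conditional_independence_test <- function(y, x, z, n_permutations = 1000,
                                          n_neighbors = 10, seed = NULL) {
  x <- as.matrix(x); z <- as.matrix(z)
  n <- length(y)
  if (nrow(x) != n || nrow(z) != n) stop("y, x, z must have matched lengths")
  if (ncol(z) < 1) stop("z needs at least one feature")
  if (n <= n_neighbors)
    stop("fewer observations than the neighbor count; reduce n_neighbors")
  Ux <- ucenter(as.matrix(dist(x)))
  Uy <- ucenter(label_distance(y))
  stat <- udcorr_stat(Ux, Uy)
  Dz <- as.matrix(dist(z))
  diag(Dz) <- Inf
  nb <- t(apply(Dz, 1, function(r) order(r)[seq_len(n_neighbors)]))
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_permutations)) {
    pidx <- seq_len(n)
    for (i in sample.int(n)) {
      j <- nb[i, sample.int(n_neighbors, 1)]
      tmp <- pidx[i]; pidx[i] <- pidx[j]; pidx[j] <- tmp
    }
    # permute Y locally in Z-space, keep X fixed
    Uyp <- Uy[pidx, pidx]
    if (udcorr_stat(Ux, Uyp) >= stat - 1e-12) cnt <- cnt + 1L
  }
  test_outcome(stat, (1 + cnt) / (n_permutations + 1), "conditional_dcorr_local_perm",
               n_permutations = n_permutations)
}

# ---- multiplicity correction --------------------------------------------

#' Adjust p-values for multiple comparisons
#'
#' Holm step-down (default; controls the family-wise error rate with no
#' independence assumption), Bonferroni, or Benjamini-Hochberg step-up
#' (false discovery rate).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method one of `"holm"`, `"bonferroni"`, `"benjamini_hochberg"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0,1]")
  p.adjust(p, method = c(holm = "holm", bonferroni = "bonferroni",
                         benjamini_hochberg = "BH")[[method]])
}
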