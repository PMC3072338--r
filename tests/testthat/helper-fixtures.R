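# in-code fixtures shared across test files

# small replicate-structured matrix from a gene x time matrix of means;
# duplicates get +/- `spread` on the linear scale (so the mean is exact)
toy_expr <- function(means, spread = 0, present = NULL) {
  n <- nrow(means)
  labels <- colnames(means)
  lev <- matrix(0, n, 2 * ncol(means),
                dimnames = list(rownames(means),
                                as.vector(t(outer(labels, 1:2, paste, sep = "_")))))
  for (j in seq_along(labels)) {
    lev[, 2 * j - 1] <- means[, j] + spread
    lev[, 2 * j] <- means[, j] - spread
  }
  expression_matrix(lev, present = present)
}

# exactly-orthogonal planted log matrix: baseline + patterns with zero-mean,
# mutually orthogonal time profiles and gene weights orthonormalized against
# the constant vector, the baseline, and each other
planted_log_matrix <- function(n = 300, profiles = list(), baseline = NULL,
                               seed = 42) {
  set.seed(seed)
  A <- if (length(profiles)) length(profiles[[1]]) else 4L
  if (is.null(baseline)) baseline <- rnorm(n, 5, 1)
  K <- length(profiles)
  G <- NULL
  if (K > 0) {
    W <- matrix(rnorm(n * K), n)
    Q <- qr.Q(qr(cbind(rep(1, n), baseline, W)))
    G <- Q[, 2 + seq_len(K), drop = FALSE]
    for (k in seq_len(K)) if (sum(G[, k] * W[, k]) < 0) G[, k] <- -G[, k]
  }
  L <- if (K > 0) do.call(rbind, profiles) else matrix(0, 0, A)
  L <- L - rowMeans(L)                       # orthogonal to the constant
  if (K > 1) {                               # mutual Gram-Schmidt
    for (k in 2:K) for (j in 1:(k - 1)) {
      L[k, ] <- L[k, ] - (sum(L[k, ] * L[j, ]) / sum(L[j, ]^2)) * L[j, ]
    }
  }
  Y <- matrix(baseline, n, A)
  if (K > 0) Y <- Y + G %*% L
  dimnames(Y) <- list(sprintf("g%03d", 1:n), as.character(seq_len(A)))
  list(Y = log_matrix(Y), G = G, L = L, baseline = baseline)
}

expect_tibble <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
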