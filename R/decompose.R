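#' Surprisal decomposition of a log expression matrix
#'
#' Fits the maximal-entropy expansion of time-course gene expression: the
#' natural log of every gene's level is written as a time-invariant baseline
#' term plus a sum of time-varying transcription patterns,
#' `ln X_i(t) = sum_a G_ia * lambda_a(t)`. The fit is the economy singular
#' value decomposition of the *non-mean-centered* gene-by-time log matrix
#' `Y = U S V'`: the columns of `U` are the per-gene pattern weights `G`, the
#' singular values are the time-independent pattern magnitudes `omega`, the
#' rows of `V'` are the unit-norm fractional time profiles `P`, and the
#' Lagrange multipliers are `lambda_a(t) = omega_a * P_a(t)`. With an
#' A-time-point trajectory exactly A patterns exist (indexed `0 .. A-1`,
#' ranked by decreasing `omega`), and using all of them reproduces the data
#' exactly, noise and all.
#'
#' Singular-vector signs are arbitrary, so a fixed convention is applied: each
#' profile is flipped so its largest-magnitude entry is positive, and the
#' baseline profile is additionally required to have positive mean (so
#' `lambda_0 > 0`). The top-magnitude pattern is accepted as the
#' time-invariant baseline only when its fractional profile is close to
#' constant (coefficient of variation at most `cv_baseline`); otherwise the
#' decomposition is returned with `alpha0` unset and a warning, since
#' constancy of the baseline is a check on the theory, not an imposition.
#'
#' @param y A [log_matrix()] (or an `expr_mat` already averaged to one column
#'   per time label, which is log-transformed with `floor = "auto"` first).
#' @param cv_baseline Maximum coefficient of variation of the leading
#'   fractional profile for it to be accepted as the time-invariant baseline.
#' @return An object of class `surprisal_fit` with elements `G` (gene x
#'   pattern, orthonormal columns), `lambda` (pattern x time), `omega`
#'   (non-negative, decreasing), `P` (pattern x time, orthonormal rows),
#'   `alpha0` (index of the baseline pattern, normally 0, or `NA`),
#'   `gene_ids`, `time_labels`, and the input log matrix `Y`.
#' @export
surprisal_decompose <- function(y, cv_baseline = 0.2) {
  if (inherits(y, "expr_mat")) y <- log_transform(y)
  stopifnot(inherits(y, "log_mat"))
  Y <- y$values
  n <- nrow(Y)
  A <- ncol(Y)
  if (n < A) {
    stop("fewer genes than time points; the decomposition assumes genes >> ",
         "time points", call. = FALSE)
  }
  sv <- svd(Y, nu = A, nv = A)
  G <- sv$u
  omega <- sv$d
  P <- t(sv$v)

  # deterministic sign convention (SVD signs are arbitrary)
  for (a in seq_len(A)) {
    flip <- if (a == 1L && abs(mean(P[a, ])) > .Machine$double.eps) {
      mean(P[a, ]) < 0
    } else {
      P[a, which.max(abs(P[a, ]))] < 0
    }
    if (flip) {
      P[a, ] <- -P[a, ]
      G[, a] <- -G[, a]
    }
  }

  if (A >= 2L && omega[1] > 0) {
    rel_gap <- diff(-omega) / omega[1]
    if (any(rel_gap < 1e-8)) {
      warning("near-equal singular values: the split between patterns ",
              paste(which(rel_gap < 1e-8) - 1L, collapse = ", "),
              " and their successors is not unique", call. = FALSE)
    }
    if (any(omega < 1e-10 * omega[1])) {
      warning("rank-deficient input: ", sum(omega < 1e-10 * omega[1]),
              " trailing pattern(s) have (numerically) zero weight",
              call. = FALSE)
    }
  }

  lambda <- omega * P
  pat <- as.character(seq_len(A) - 1L)
  dimnames(G) <- list(y$gene_ids, pat)
  dimnames(P) <- list(pat, y$time_labels)
  dimnames(lambda) <- list(pat, y$time_labels)
  names(omega) <- pat

  p0 <- P[1, ]
  cv0 <- if (abs(mean(p0)) < .Machine$double.eps) Inf else stats::sd(p0) / abs(mean(p0))
  alpha0 <- 0L
  if (cv0 > cv_baseline) {
    alpha0 <- NA_integer_
    warning(sprintf(paste0("dominant pattern is not time-invariant (fractional-",
                           "profile CV %.3g > %.3g); no baseline identified"),
                    cv0, cv_baseline), call. = FALSE)
  }

  structure(
    list(G = G, lambda = lambda, omega = omega, P = P, alpha0 = alpha0,
         gene_ids = y$gene_ids, time_labels = y$time_labels, Y = Y,
         floor_used = y$floor_used),
    class = "surprisal_fit"
  )
}

#' @export
print.surprisal_fit <- function(x, ...) {
  A <- length(x$omega)
  cat(sprintf("<surprisal_fit> %d genes, %d time points, %d patterns (alpha = 0..%d)\n",
              nrow(x$G), A, A, A - 1L))
  cat("  omega:", paste(signif(x$omega, 4), collapse = " "), "\n")
  cat("  baseline pattern:",
      if (is.na(x$alpha0)) "not identified" else x$alpha0, "\n")
  invisible(x)
}

pattern_row <- function(fit, alpha) {
  A <- length(fit$omega)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > A - 1L) {
    stop("`alpha` must be a single pattern index in 0..", A - 1L, call. = FALSE)
  }
  as.integer(alpha) + 1L
}

time_col <- function(fit, label) {
  i <- match(as.character(label), fit$time_labels)
  if (is.na(i)) {
    stop("unknown time label '", label, "'; trajectory has: ",
         paste(fit$time_labels, collapse = ", "), call. = FALSE)
  }
  i
}

#' Factorize pattern weights into magnitude and fractional time profile
#'
#' Splits each Lagrange-multiplier row `lambda_a(t)` into a time-independent
#' magnitude `omega_a >= 0` and a unit-norm fractional time profile `P_a`,
#' with `lambda_a(t) = omega_a * P_a(t)` entrywise. For a fitted
#' decomposition these are the singular values and right singular vectors; the
#' matrix method recomputes them from any pattern-by-time matrix.
#'
#' @param x A `surprisal_fit` or a numeric pattern-by-time matrix of lambda
#'   values.
#' @param ... Unused.
#' @return A list with `omega` (non-negative vector), `P` (unit-row matrix;
#'   all-zero lambda rows give zero rows), and `degenerate` (logical vector
#'   flagging the all-zero rows, whose profile is undefined).
#' @export
factorize_weights <- function(x, ...) UseMethod("factorize_weights")

#' @rdname factorize_weights
#' @export
factorize_weights.surprisal_fit <- function(x, ...) {
  factorize_weights(x$lambda)
}

#' @rdname factorize_weights
#' @export
factorize_weights.matrix <- function(x, ...) {
  omega <- sqrt(rowSums(x^2))
  P <- x
  nz <- omega > 0
  P[nz, ] <- x[nz, , drop = FALSE] / omega[nz]
  P[!nz, ] <- 0
  list(omega = omega, P = P, degenerate = !nz)
}

#' @rdname factorize_weights
#' @export
factorize_weights.default <- function(x, ...) {
  factorize_weights(matrix(x, nrow = 1L,
                           dimnames = list("0", seq_along(x))))
}

varying_order <- function(fit) {
  # time-varying patterns (baseline excluded), in decreasing omega order
  idx <- seq_along(fit$omega)
  if (!is.na(fit$alpha0)) idx <- idx[idx != fit$alpha0 + 1L]
  idx[order(-fit$omega[idx])]
}

#' Reconstruct log expression from the leading patterns
#'
#' Rebuilds predicted natural-log levels from the baseline pattern plus the
#' `k` most important time-varying patterns. With `k = A - 1` (all patterns)
#' the reconstruction reproduces the input exactly; small `k` shows how few
#' patterns already account for the data.
#'
#' @param d A `surprisal_fit`.
#' @param k Number of time-varying patterns to include, `0 .. A-1`.
#' @return A [log_matrix()] of predicted log levels, with a per-time-point
#'   R-squared (against the input matrix) in `attr(, "r_squared")`.
#' @export
reconstruct <- function(d, k) {
  stopifnot(inherits(d, "surprisal_fit"))
  A <- length(d$omega)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > A - 1L) {
    stop("`k` must be in 0..", A - 1L, " (number of time-varying patterns)",
         call. = FALSE)
  }
  base <- if (is.na(d$alpha0)) 1L else d$alpha0 + 1L
  idx <- c(base, utils::head(varying_order(d), k))
  Yhat <- d$G[, idx, drop = FALSE] %*% d$lambda[idx, , drop = FALSE]
  dimnames(Yhat) <- dimnames(d$Y)
  r2 <- vapply(seq_len(ncol(Yhat)), function(j) {
    ss_tot <- sum((d$Y[, j] - mean(d$Y[, j]))^2)
    if (ss_tot == 0) return(1)
    1 - sum((Yhat[, j] - d$Y[, j])^2) / ss_tot
  }, numeric(1))
  names(r2) <- d$time_labels
  out <- log_matrix(Yhat, floor_used = d$floor_used)
  attr(out, "r_squared") <- r2
  out
}

#' Per-gene change in log expression between two time points
#'
#' Evaluates, for every gene, the pattern-resolved change
#' `sum_a G_ia * (lambda_a(t') - lambda_a(t))` over a chosen subset of
#' patterns. With all patterns included this equals the direct difference of
#' log expression columns exactly; restricted to one pattern it isolates that
#' pattern's contribution to the change (the quantity gene selection
#' thresholds on).
#'
#' @param d A `surprisal_fit`.
#' @param time_from,time_to Time labels `t` and `t'` within the trajectory
#'   (equal labels give a zero vector).
#' @param alphas Pattern indices (0-based) to include; `NULL` means all.
#' @return A named numeric vector over genes.
#' @export
delta_expression <- function(d, time_from, time_to, alphas = NULL) {
  stopifnot(inherits(d, "surprisal_fit"))
  i <- time_col(d, time_from)
  j <- time_col(d, time_to)
  rows <- if (is.null(alphas)) {
    seq_along(d$omega)
  } else {
    vapply(alphas, function(a) pattern_row(d, a), integer(1))
  }
  dl <- d$lambda[rows, j] - d$lambda[rows, i]
  out <- as.vector(d$G[, rows, drop = FALSE] %*% dl)
  names(out) <- d$gene_ids
  out
}

#' Check the theoretical constancy of the baseline multiplier
#'
#' The multiplier of the time-invariant (maximal-entropy) pattern,
#' `lambda_0(t)`, should not depend on time; the fit lets it vary and uses its
#' near-constancy as a numerical validation. This computes `lambda_0` per time
#' point and its coefficient of variation.
#'
#' @param d A `surprisal_fit` with an identified baseline pattern.
#' @param tol_cv Pass threshold on the coefficient of variation.
#' @return An object of class `lambda0_report`: list with `lambda0` (named
#'   per-time vector), `cv`, `tol_cv`, `passed`.
#' @export
check_lambda0_constancy <- function(d, tol_cv = 0.05) {
  stopifnot(inherits(d, "surprisal_fit"))
  if (is.na(d$alpha0)) {
    stop("no baseline pattern identified; constancy check undefined",
         call. = FALSE)
  }
  lam0 <- d$lambda[d$alpha0 + 1L, ]
  cv <- if (abs(mean(lam0)) < .Machine$double.eps) Inf else
    stats::sd(lam0) / abs(mean(lam0))
  structure(
    list(lambda0 = lam0, cv = cv, tol_cv = tol_cv, passed = cv <= tol_cv),
    class = "lambda0_report"
  )
}

#' @export
print.lambda0_report <- function(x, ...) {
  cat("<lambda0_report>\n")
  cat("  lambda0 per time:", paste(signif(x$lambda0, 5), collapse = " "), "\n")
  cat(sprintf("  coefficient of variation: %.4g (tolerance %.4g) -> %s\n",
              x$cv, x$tol_cv, if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Entropy deficiency of the expression distribution at each time point
#'
#' Measures how far the expression distribution at a time point is from the
#' maximal-entropy baseline: the Kullback-Leibler divergence
#' `D(T) = sum_i p_i(T) * ln(p_i(T) / p0_i)`, where `p(T)` are the levels at
#' time T normalized to sum one and `p0` is the normalized baseline
#' distribution `exp(lambda_0(T) * G_i0)`. `D` is non-negative, zero exactly
#' when no time-varying constraint is active, and - because entropy is a
#' state function - depends only on the current levels: computing it from the
#' raw column or from the all-pattern reconstruction gives the same value.
#'
#' @param d A `surprisal_fit` with an identified baseline pattern.
#' @param time Time label(s); `NULL` (default) computes all.
#' @param from `"levels"` (the input log matrix) or `"reconstruction"` (the
#'   all-pattern reconstruction).
#' @return A tibble with columns `time_label`, `deficiency`.
#' @export
entropy_deficiency <- function(d, time = NULL,
                               from = c("levels", "reconstruction")) {
  stopifnot(inherits(d, "surprisal_fit"))
  from <- match.arg(from)
  if (is.na(d$alpha0)) {
    stop("no baseline pattern identified; entropy deficiency undefined",
         call. = FALSE)
  }
  labels <- if (is.null(time)) d$time_labels else as.character(time)
  Y <- if (from == "levels") d$Y else
    reconstruct(d, k = length(d$omega) - 1L)$values
  g0 <- d$G[, d$alpha0 + 1L]
  defic <- vapply(labels, function(label) {
    j <- time_col(d, label)
    logp <- Y[, j] - logsumexp(Y[, j])
    base <- d$lambda[d$alpha0 + 1L, j] * g0
    if (any(exp(base) == 0)) {
      stop("baseline distribution underflows to zero; floor levels upstream",
           call. = FALSE)
    }
    logp0 <- base - logsumexp(base)
    sum(exp(logp) * (logp - logp0))
  }, numeric(1))
  tibble::tibble(time_label = labels, deficiency = unname(defic))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
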