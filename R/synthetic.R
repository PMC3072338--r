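#' Specify a synthetic time-course expression data set
#'
#' Describes data generated by running the surprisal expansion forward: a
#' heterogeneous time-invariant baseline (the maximal-entropy state is not
#' uniform), a small number of planted time-varying transcription patterns
#' with chosen time profiles (including mid-course sign flips), lognormal
#' replicate noise, and full ground truth for recovery tests.
#'
#' Profile values are on the per-gene natural-log scale: a profile value `a`
#' means a typical gene (one weight standard deviation) moves by about
#' `a * gene_weight_sd` ln-units at that time point. By default profiles are
#' centered over time and mutually orthogonalized, and gene-weight columns
#' are orthonormalized against the constant gene vector, the baseline, and
#' each other; this generator convention makes the planted structure coincide
#' with the decomposition's orthogonality contract, so that zero-noise
#' recovery is exact and the planted baseline multiplier is exactly constant.
#' It is a numerical convention, not a biological claim.
#'
#' @param n_genes Number of genes.
#' @param time_labels Ordered character vector of time-point labels.
#' @param pattern_profiles List of numeric vectors (one per planted
#'   time-varying pattern, each of length `length(time_labels)`).
#' @param baseline_mean,baseline_sd Mean and sd of the per-gene baseline on
#'   the ln scale.
#' @param gene_weight_sd Per-gene effect scale of the planted patterns (ln
#'   units per unit profile value).
#' @param replicate_noise_sd Additive noise sd on the ln scale per replicate
#'   (multiplicative lognormal on levels).
#' @param n_replicates Replicates per time point (duplicates by default).
#' @param seed Integer seed; a fixed seed reproduces the data bit-for-bit.
#' @param center_profiles Center each profile to zero time-mean.
#' @param orthogonalize_profiles Gram-Schmidt the profiles against each other.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000,
                           time_labels = as.character(1:6),
                           pattern_profiles = list(),
                           baseline_mean = 5, baseline_sd = 1,
                           gene_weight_sd = 1,
                           replicate_noise_sd = 0.05,
                           n_replicates = 2, seed = 1,
                           center_profiles = TRUE,
                           orthogonalize_profiles = TRUE) {
  time_labels <- as.character(time_labels)
  A <- length(time_labels)
  K <- length(pattern_profiles)
  stopifnot(n_genes >= 2, A >= 2, n_replicates >= 1,
            baseline_sd >= 0, replicate_noise_sd >= 0, gene_weight_sd >= 0)
  if (K >= A) {
    stop("number of planted patterns (", K, ") must be below the number of ",
         "time points (", A, "): the model is unidentifiable otherwise",
         call. = FALSE)
  }
  bad <- which(lengths(pattern_profiles) != A)
  if (length(bad)) {
    stop("pattern profile ", bad[1], " has length ",
         lengths(pattern_profiles)[bad[1]], ", expected ", A, call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), time_labels = time_labels,
         n_patterns = K, pattern_profiles = pattern_profiles,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         gene_weight_sd = gene_weight_sd,
         replicate_noise_sd = replicate_noise_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         center_profiles = center_profiles,
         orthogonalize_profiles = orthogonalize_profiles),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic expression matrix with planted surprisal structure
#'
#' Draws the baseline and gene weights, forms
#' `ln X = baseline + sum_a lambda_a(t) * G_a`, adds per-replicate noise on
#' the ln scale, exponentiates, and emits a replicate-structured expression
#' matrix with all-present call flags plus the planted ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (an `expr_mat`) and `truth` (class
#'   `surprisal_truth`: `true_G` gene x pattern with orthonormal columns
#'   including the baseline as pattern 0; `true_lambda` pattern x time;
#'   `true_omega`; `true_P` unit-norm profiles; `true_inversions` tibble of
#'   planted sign flips).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_genes
  A <- length(spec$time_labels)
  K <- spec$n_patterns
  gene_ids <- sprintf("g%04d", seq_len(n))

  b <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)

  G <- matrix(0, nrow = n, ncol = 0)
  if (K > 0) {
    W <- matrix(stats::rnorm(n * K), nrow = n)
    Q <- qr.Q(qr(cbind(rep(1, n), b, W)))
    G <- Q[, 2L + seq_len(K), drop = FALSE]
    for (k in seq_len(K)) {             # deterministic orientation
      if (crossprod(G[, k], W[, k]) < 0) G[, k] <- -G[, k]
    }
  }

  L <- do.call(rbind, spec$pattern_profiles)
  if (K > 0) {
    if (spec$center_profiles) L <- L - rowMeans(L)
    if (spec$orthogonalize_profiles && K > 1) {
      for (k in 2:K) {
        for (j in 1:(k - 1)) {
          denom <- sum(L[j, ]^2)
          if (denom > 0) L[k, ] <- L[k, ] - (sum(L[k, ] * L[j, ]) / denom) * L[j, ]
        }
      }
    }
    lambda_varying <- L * sqrt(n) * spec$gene_weight_sd
  } else {
    lambda_varying <- matrix(0, nrow = 0, ncol = A)
  }

  lnX <- matrix(b, nrow = n, ncol = A)
  if (K > 0) lnX <- lnX + G %*% lambda_varying

  cols <- as.vector(t(outer(spec$time_labels, seq_len(spec$n_replicates),
                            paste, sep = "_")))
  lev <- matrix(0, nrow = n, ncol = length(cols),
                dimnames = list(gene_ids, cols))
  for (tj in seq_len(A)) {
    for (r in seq_len(spec$n_replicates)) {
      noise <- if (spec$replicate_noise_sd > 0)
        stats::rnorm(n, 0, spec$replicate_noise_sd) else 0
      lev[, (tj - 1L) * spec$n_replicates + r] <- exp(lnX[, tj] + noise)
    }
  }
  present <- matrix(TRUE, nrow = n, ncol = ncol(lev), dimnames = dimnames(lev))
  m <- expression_matrix(lev, present = present)

  lam0 <- sqrt(sum(b^2))
  true_G <- cbind(b / lam0, G)
  true_lambda <- rbind(rep(lam0, A), lambda_varying)
  pat <- as.character(0:K)
  dimnames(true_G) <- list(gene_ids, pat)
  dimnames(true_lambda) <- list(pat, spec$time_labels)
  fw <- factorize_weights(true_lambda)
  dimnames(fw$P) <- dimnames(true_lambda)
  names(fw$omega) <- pat

  truth <- structure(
    list(true_G = true_G, true_lambda = true_lambda,
         true_omega = fw$omega, true_P = fw$P,
         true_inversions = planted_inversions(true_lambda, spec$time_labels),
         spec = spec),
    class = "surprisal_truth"
  )
  list(matrix = m, truth = truth)
}

planted_inversions <- function(true_lambda, time_labels, tol = 1e-9) {
  K1 <- nrow(true_lambda)
  out <- list()
  for (a in seq_len(K1)[-1]) {     # skip the baseline row
    lam <- true_lambda[a, ]
    nz <- which(abs(lam) > tol * max(abs(lam), 1))
    if (length(nz) < 2L) next
    i <- nz[-length(nz)]; j <- nz[-1L]
    fl <- sign(lam[i]) != sign(lam[j])
    if (any(fl)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        pattern = a - 1L,
        time_before = time_labels[i[fl]],
        time_after = time_labels[j[fl]]
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(pattern = integer(), time_before = character(),
                   time_after = character())
}

#' Planted contributing genes for a pattern between two time points
#'
#' Derives from the ground truth which genes the single-pattern change
#' `G_ia * (lambda_a(t') - lambda_a(t))` moves by at least `threshold`
#' ln-units, mirroring [select_contributing_genes()] on the planted values.
#'
#' @param truth A `surprisal_truth`.
#' @param alpha Planted pattern index (1-based over the time-varying
#'   patterns, i.e. 1 is the first planted pattern).
#' @param time_from,time_to Time labels.
#' @param threshold Cutoff on the ln scale (default 0.5).
#' @return A tibble: `gene_id`, `pattern`, `delta_ln`, `direction`.
#' @export
true_contributing_genes <- function(truth, alpha, time_from, time_to,
                                    threshold = 0.5) {
  stopifnot(inherits(truth, "surprisal_truth"))
  row <- as.character(alpha)
  dl <- truth$true_lambda[row, time_to] - truth$true_lambda[row, time_from]
  term <- truth$true_G[, row] * dl
  sel <- abs(term) >= threshold
  tibble::tibble(
    gene_id = rownames(truth$true_G)[sel],
    pattern = as.integer(alpha),
    delta_ln = unname(term[sel]),
    direction = dplyr::if_else(term[sel] > 0, "induced", "reduced")
  )
}

#' A WI-38-like branching time course with known structure
#'
#' Builds a 12-time-point, duplicate-measured, 2000-gene data set emulating a
#' branching cell-transformation design: a dominant heterogeneous baseline;
#' pattern 1 constant-positive through label 7 then flipping sign at label 8;
#' pattern 2 active only over labels 1-7 (rising through label 7, zero
#' afterwards); pattern 3 active only over labels 8-12 with a sign change
#' before the last label. The branching routes (three trajectories sharing
#' the prefix 1-5-7-8, a short 1-5-6 branch, and an independent 1-3-4 route)
#' are column subsets of the one matrix, so shared stages share values by
#' construction.
#'
#' @param n_genes Number of genes (default 2000).
#' @param replicate_noise_sd Ln-scale replicate noise sd (default 0.05; use 0
#'   for the noiseless variant).
#' @param seed Integer seed (default 38).
#' @return A list with `matrix` (`expr_mat`), `truth` (`surprisal_truth`),
#'   and `trajectories` (character vector of route strings).
#' @export
make_wi38_like_fixture <- function(n_genes = 2000, replicate_noise_sd = 0.05,
                                   seed = 38) {
  profiles <- list(
    c(rep(1.5, 7), rep(-2.1, 5)),                               # flips at 7->8
    c(-1.5, -1.3, -1.0, -0.6, 0.5, 1.5, 2.4, rep(0, 5)),        # early only
    c(rep(0, 7), 0.5, 0.8, 0.6, -0.35, -1.55)                   # late only
  )
  spec <- synthetic_spec(
    n_genes = n_genes, time_labels = as.character(1:12),
    pattern_profiles = profiles,
    baseline_mean = 5, baseline_sd = 1, gene_weight_sd = 1,
    replicate_noise_sd = replicate_noise_sd, n_replicates = 2, seed = seed
  )
  sim <- simulate_expression(spec)
  sim$trajectories <- c("1-5-7-8-9", "1-5-7-8-10-12", "1-5-7-8-11",
                        "1-5-6", "1-3-4")
  sim
}
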