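fit_from_lambda <- function(lam, n = 60, seed = 8) {
  # build a fit whose varying lambda rows are exactly `lam` by planting them
  profiles <- lapply(seq_len(nrow(lam)), function(i) lam[i, ])
  pl <- planted_log_matrix(n = n, profiles = profiles, seed = seed)
  suppressWarnings(surprisal_decompose(pl$Y))
}

test_that("patterns are ranked by decreasing importance, baseline excluded", {
  pl <- planted_log_matrix(n = 300, profiles = list(
    c(4, 4, -4, -4, 0, 0) * 2, c(0, 2, 2, -2, -2, 0) * 2, c(1, -1, 0, 0, 1, -1) * 2
  ), seed = 17)
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  rk <- rank_patterns(fit)
  expect_tibble(rk, c("rank", "pattern", "omega"))
  expect_false(0L %in% rk$pattern)
  expect_true(all(diff(rk$omega) <= 0))
  # planted omega ratios survive: pattern ranking matches profile norms 4:2:1-ish
  expect_identical(rk$pattern[1:3], c(1L, 2L, 3L))
  norms <- sqrt(rowSums(pl$L^2))
  expect_equal(rk$omega[1:3] / rk$omega[1], norms / norms[1], tolerance = 1e-8)
})

test_that("tied importances warn and keep a stable order", {
  lam <- rbind(c(2, 2, -2, -2), c(2, -2, 2, -2))  # equal norms
  fit <- fit_from_lambda(lam)
  expect_warning(rk <- rank_patterns(fit), "tied")
  expect_identical(rk$pattern[1:2], c(1L, 2L))
})

# a fit whose varying lambda row is set verbatim, to exercise the scanner on
# hand-written sequences that a zero-mean planted profile cannot realize
fit_with_lambda <- function(values) {
  f <- fit_from_lambda(rbind(seq_along(values) - mean(seq_along(values))))
  f$lambda[2, ] <- values
  f
}

test_that("inversions are sign changes between consecutive above-floor points", {
  f1 <- fit_from_lambda(rbind(c(2, 1, 0.5, -3.5) * 2))
  # planted profile stays one-signed until the last step: exactly one event
  ev <- detect_inversions(f1, 1)
  expect_identical(nrow(ev), 1L)

  no_flip <- fit_with_lambda(c(2, 1, 0.5))
  expect_identical(nrow(detect_inversions(no_flip, 1, noise_floor = 0)), 0L)
  one_flip <- fit_with_lambda(c(2, 1, -2))
  ev1 <- detect_inversions(one_flip, 1)
  expect_identical(ev1$time_before, "2")
  expect_identical(ev1$time_after, "3")
})

test_that("hand-enumerated flips are found, including across a near-zero point", {
  f <- fit_with_lambda(c(2, 1, -2, -1))
  ev <- detect_inversions(f, 1, noise_floor = 0.1 * max(abs(f$lambda[2, ])))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$time_before, "2")
  expect_identical(ev$time_after, "3")
  expect_false(ev$spans_below_floor)
  expect_true(sign(ev$lambda_before) != sign(ev$lambda_after))
  expect_equal(ev$magnitude, abs(ev$lambda_after - ev$lambda_before))

  fz <- fit_with_lambda(c(2, 0.001, -2))
  evz <- detect_inversions(fz, 1, noise_floor = 0.1 * max(abs(fz$lambda[2, ])))
  # the near-zero middle point is skipped: the event spans it and is flagged
  expect_identical(nrow(evz), 1L)
  expect_identical(evz$time_before, "1")
  expect_identical(evz$time_after, "3")
  expect_true(evz$spans_below_floor)
})

test_that("inversion calls are sign-symmetric and bounded by A - 1", {
  for (seed in c(2, 3, 4)) {
    set.seed(seed)
    prof <- rnorm(6, sd = 2)
    f <- fit_from_lambda(rbind(prof), seed = seed)
    lam <- f$lambda[2, ]
    ev <- detect_inversions(f, 1)
    # mirrored profile: feed the scanner the negated fit via a sign flip
    fneg <- f
    fneg$lambda[2, ] <- -lam
    evneg <- detect_inversions(fneg, 1)
    expect_identical(evneg$time_before, ev$time_before)
    expect_identical(evneg$time_after, ev$time_after)
    expect_equal(evneg$lambda_before, -ev$lambda_before)
    expect_equal(evneg$lambda_after, -ev$lambda_after)
    expect_lte(nrow(ev), length(lam) - 1L)
  }
})

test_that("the baseline pattern is refused by the inversion detector", {
  f <- fit_from_lambda(rbind(c(1, 1, -1, -1)))
  expect_error(detect_inversions(f, 0), "baseline")
})

test_that("contributing genes are exactly the planted over-threshold set", {
  # construct data where the planted per-gene terms are known exactly, then
  # scale so that exactly 37 genes clear the 0.5 cutoff
  set.seed(23)
  n <- 300
  b <- rnorm(n, 5, 1)
  W <- rnorm(n)
  Q <- qr.Q(qr(cbind(rep(1, n), b, W)))
  g <- Q[, 3] * sign(sum(Q[, 3] * W))
  prof <- c(1, 1, -1, -1)
  term0 <- g * (prof[3] - prof[1])           # unscaled planted terms, 1 -> 3
  ord <- sort(abs(term0), decreasing = TRUE)
  scale <- 0.5 / mean(ord[37:38])            # puts the cut between ranks 37/38
  Y <- matrix(b, n, 4) + outer(g, prof * scale)
  dimnames(Y) <- list(sprintf("g%03d", 1:n), as.character(1:4))
  fit <- suppressWarnings(surprisal_decompose(log_matrix(Y)))
  expected <- rownames(Y)[abs(term0 * scale) >= 0.5]
  expect_length(expected, 37L)

  sel <- select_contributing_genes(fit, 1, "1", "3", threshold = 0.5)
  expect_setequal(sel$gene_id, expected)
  expect_identical(unique(sel$pattern), 1L)
  expect_true(all(sel$direction[sel$delta_ln > 0] == "induced"))
  expect_true(all(sel$direction[sel$delta_ln < 0] == "reduced"))
  expect_true(all(abs(sel$delta_ln) >= 0.5))

  # swapping the two time points swaps induced and reduced exactly
  swapped <- select_contributing_genes(fit, 1, "3", "1", threshold = 0.5)
  expect_setequal(swapped$gene_id, sel$gene_id)
  m <- merge(as.data.frame(sel), as.data.frame(swapped), by = "gene_id")
  expect_true(all(m$delta_ln.x == -m$delta_ln.y))
  expect_true(all(m$direction.x != m$direction.y))
})

test_that("the p-value gate and threshold contract are enforced", {
  f <- fit_from_lambda(rbind(c(1.2, 0.4, -0.4, -1.2)))
  expect_error(select_contributing_genes(f, 1, "1", "4", threshold = 0),
               "positive")
  all_sel <- select_contributing_genes(f, 1, "1", "4", threshold = 0.2)
  pv <- stats::setNames(rep(0.01, length(f$gene_ids)), f$gene_ids)
  gated <- select_contributing_genes(f, 1, "1", "4", threshold = 0.2,
                                     pvals = pv)   # all "fail" under p >= cut
  expect_identical(nrow(gated), 0L)
  gated_lt <- select_contributing_genes(f, 1, "1", "4", threshold = 0.2,
                                        pvals = pv, p_rule = "lt")
  expect_identical(gated_lt$gene_id, all_sel$gene_id)
})

test_that("pattern alignment recovers identity, sign flips, and shared plantings", {
  pl <- planted_log_matrix(n = 250, profiles = list(c(2, 2, -2, -2),
                                                    c(1, -1, -1, 1)), seed = 31)
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  al <- align_patterns(fit, fit)
  expect_identical(al$pattern_a, al$pattern_b)
  expect_equal(al$cosine, rep(1, length(al$cosine)))

  flipped <- fit
  flipped$G[, 2] <- -flipped$G[, 2]
  al2 <- align_patterns(fit, flipped)
  expect_equal(al2$sign[al2$pattern_a == 1], -1)
  expect_equal(abs(al2$cosine), rep(1, nrow(al2)), tolerance = 1e-12)

  al3 <- align_patterns(fit, flipped, method = "optimal")
  expect_identical(al3$pattern_b, al2$pattern_b)

  other <- fit
  other$gene_ids <- c(other$gene_ids[-1], "extra")
  expect_error(align_patterns(fit, other), "intersect")
})

test_that("two noisy realizations of shared planted patterns align", {
  profiles <- list(c(3, 3, -3, -3, 0, 0), c(0, 1.5, 1.5, -1.5, -1.5, 0))
  # each noisy realization must still recover the shared planted profiles
  for (s in c(1, 2)) {
    sim <- simulate_expression(synthetic_spec(
      n_genes = 400, time_labels = as.character(1:6),
      pattern_profiles = profiles, replicate_noise_sd = 0.05, seed = s
    ))
    fit <- suppressWarnings(surprisal_decompose(
      log_transform(average_replicates(sim$matrix))))
    for (a in 2:3) {
      cs <- abs(fit$P %*% sim$truth$true_P[a, ])
      expect_gte(max(cs), 0.95)
    }
  }
})
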