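test_that("log transform handles exact values, zeros, and the strict floor", {
  m <- expression_matrix(matrix(exp(1), 2, 2,
                                dimnames = list(c("a", "b"), c("1", "2"))))
  m <- average_replicates(m)
  expect_equal(unname(log_transform(m)$values[1, 1]), 1)

  mz <- average_replicates(expression_matrix(
    matrix(c(0, 4), 2, 2, dimnames = list(c("a", "b"), c("1", "2")))))
  y1 <- log_transform(mz, floor = 1)
  expect_identical(unname(y1$values["a", ]), c(0, 0))   # ln 1
  yauto <- log_transform(mz)
  expect_equal(yauto$floor_used, 2)                      # half of min positive
  expect_error(log_transform(mz, floor = "strict"), "strict")

  # closed form: exp(k) grid comes back as the integer grid exactly
  k <- matrix(c(-2:3), 2, 3, dimnames = list(c("a", "b"), c("1", "2", "3")))
  mk <- average_replicates(expression_matrix(exp(k)))
  expect_equal(log_transform(mk)$values, k)
})

test_that("a constant matrix decomposes into the rank-1 closed form", {
  n <- 50; A <- 4; cval <- 3
  Y <- log_matrix(matrix(cval, n, A, dimnames = list(sprintf("g%02d", 1:n),
                                                     as.character(1:A))))
  fit <- suppressWarnings(surprisal_decompose(Y))
  expect_equal(unname(fit$omega[1]), cval * sqrt(n * A))
  expect_equal(unname(fit$G[, 1]), rep(1 / sqrt(n), n))
  expect_equal(unname(fit$P[1, ]), rep(1 / sqrt(A), A))
  expect_equal(unname(fit$omega[-1]), rep(0, A - 1), tolerance = 1e-10)
  expect_identical(fit$alpha0, 0L)
})

test_that("a planted rank-2 matrix is recovered: singular values and subspace", {
  set.seed(7)
  n <- 200
  g0 <- rep(1 / sqrt(n), n)
  g1 <- rnorm(n); g1 <- g1 - sum(g1 * g0) * g0; g1 <- g1 / sqrt(sum(g1^2))
  l0 <- c(4, 4, 4, 4) * 10
  l1 <- c(1, 2, -1, -2)                 # orthogonal to l0
  Y <- outer(g0, l0) + outer(g1, l1)
  dimnames(Y) <- list(sprintf("g%03d", 1:n), as.character(1:4))
  fit <- suppressWarnings(surprisal_decompose(log_matrix(Y)))
  expect_equal(unname(fit$omega[1:2]),
               c(sqrt(sum(l0^2)), sqrt(sum(l1^2))), tolerance = 1e-10)
  # spans agree: projecting the planted g's onto the recovered pair is lossless
  proj <- crossprod(fit$G[, 1:2], cbind(g0, g1))
  expect_equal(colSums(proj^2), c(g0 = 1, g1 = 1), tolerance = 1e-8)
})

test_that("a 6-time-point trajectory yields exactly 6 patterns, alpha 0..5", {
  set.seed(1)
  Y <- log_matrix(matrix(rnorm(300 * 6, 5), 300, 6,
                         dimnames = list(sprintf("g%03d", 1:300),
                                         as.character(1:6))))
  fit <- suppressWarnings(surprisal_decompose(Y))
  expect_length(fit$omega, 6L)
  expect_identical(rownames(fit$lambda), as.character(0:5))
  expect_true(all(diff(fit$omega) <= 0))
})

test_that("orthonormality and the exact-representation contract hold on random input", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 150; A <- 5
    Y <- log_matrix(matrix(rnorm(n * A, 6, 1.5), n, A,
                           dimnames = list(sprintf("g%03d", 1:n),
                                           as.character(1:A))))
    fit <- suppressWarnings(surprisal_decompose(Y))
    expect_lt(max(abs(crossprod(fit$G) - diag(A))), 1e-10)
    expect_lt(max(abs(tcrossprod(fit$P) - diag(A))), 1e-10)
    expect_lt(max(abs(fit$lambda - fit$omega * fit$P)), 1e-12)
    rec <- reconstruct(fit, A - 1)
    expect_lt(max(abs(rec$values - Y$values)), 1e-8)
  }
})

test_that("weight factorization splits lambda into magnitude and unit profile", {
  fw <- factorize_weights(matrix(c(3, 4), 1, dimnames = list("1", c("1", "2"))))
  expect_equal(unname(fw$omega), 5)
  expect_equal(unname(fw$P[1, ]), c(0.6, 0.8))
  expect_false(fw$degenerate)

  fz <- factorize_weights(rbind(`1` = c(0, 0, 0)))
  expect_equal(unname(fz$omega), 0)
  expect_true(all(fz$P == 0))
  expect_true(fz$degenerate)

  set.seed(3)
  lam <- matrix(rnorm(12), 3)
  fr <- factorize_weights(lam)
  expect_equal(fr$omega * fr$P, lam, tolerance = 1e-12)
})

test_that("reconstruction quality is monotone in the number of patterns", {
  pl <- planted_log_matrix(n = 250, profiles = list(
    c(2, 2, -2, -2, 0, 0), c(0, 1.5, 1.5, -1, -1, -1), c(1, -1, 1, -1, 1, -1)
  ))
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  r2 <- vapply(0:3, function(k) mean(attr(reconstruct(fit, k), "r_squared")),
               numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_equal(r2[4], 1, tolerance = 1e-12)
  # k = 0 on data with a constant baseline returns the baseline only
  rec0 <- reconstruct(fit, 0)
  expect_equal(rec0$values,
               outer(fit$G[, 1] * fit$omega[1], fit$P[1, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(reconstruct(fit, 6), "0..5")
})

test_that("pattern-resolved deltas match the direct column difference", {
  pl <- planted_log_matrix(n = 180, profiles = list(c(1.5, 0.5, -0.5, -1.5)))
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  expect_equal(unname(delta_expression(fit, "2", "2")), rep(0, 180))
  d_all <- delta_expression(fit, "1", "3")
  expect_equal(unname(d_all), unname(pl$Y$values[, "3"] - pl$Y$values[, "1"]),
               tolerance = 1e-10)
  expect_error(delta_expression(fit, "1", "9"), "unknown time label")
})

test_that("a sign-flipping pattern inverts each gene's contribution", {
  a <- 2
  pl <- planted_log_matrix(n = 400, profiles = list(c(a, a, -a, -a)), seed = 12)
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  d1 <- delta_expression(fit, "2", "3", alphas = 1)
  # planted closed form: delta = -2a * G_i1 (fit pattern may be sign-flipped
  # jointly in G and lambda, leaving the product invariant)
  expect_equal(unname(d1), unname(-2 * a * pl$G[, 1]), tolerance = 1e-8)
  up <- pl$G[, 1] > 0
  expect_true(all(d1[up] < 0))       # highly expressed before -> fall
  expect_true(all(d1[!up] > 0))      # under-expressed before -> rise
})

test_that("lambda0 constancy validates planted baselines and flags varying ones", {
  pl <- planted_log_matrix(n = 200, profiles = list(c(1, 1, -1, -1)))
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  rep <- check_lambda0_constancy(fit)
  expect_equal(rep$cv, 0, tolerance = 1e-12)
  expect_true(rep$passed)

  # multiplicative noise keeps the CV small but nonzero
  set.seed(99)
  Yn <- pl$Y$values + matrix(rnorm(200 * 4, 0, 0.05), 200, 4)
  dimnames(Yn) <- dimnames(pl$Y$values)
  fitn <- surprisal_decompose(log_matrix(Yn))
  repn <- check_lambda0_constancy(fitn, tol_cv = 0.05)
  expect_gt(repn$cv, 0)
  expect_true(repn$passed)

  # adversarial: dominant pattern strongly time-varying -> no baseline
  set.seed(4)
  g <- rnorm(100); g <- g / sqrt(sum(g^2))
  Yv <- outer(g, c(10, -10, 9, -11)) + matrix(rnorm(400, 0, 0.01), 100, 4)
  dimnames(Yv) <- list(sprintf("g%03d", 1:100), as.character(1:4))
  expect_warning(fitv <- surprisal_decompose(log_matrix(Yv)),
                 "not time-invariant")
  expect_true(is.na(fitv$alpha0))
  expect_error(check_lambda0_constancy(fitv), "no baseline")
})

test_that("entropy deficiency is a non-negative state function, zero at baseline", {
  pl0 <- planted_log_matrix(n = 150, profiles = list())
  fit0 <- suppressWarnings(surprisal_decompose(pl0$Y))
  d0 <- entropy_deficiency(fit0)
  expect_true(all(abs(d0$deficiency) < 1e-12))

  pl <- planted_log_matrix(n = 150,
                           profiles = list(c(0.2, 0.5, -0.3, -0.4) * 3))
  fit <- suppressWarnings(surprisal_decompose(pl$Y))
  d_raw <- entropy_deficiency(fit, from = "levels")
  d_rec <- entropy_deficiency(fit, from = "reconstruction")
  expect_true(all(d_raw$deficiency >= 0))
  expect_equal(d_raw$deficiency, d_rec$deficiency, tolerance = 1e-10)
})

test_that("entropy deficiency grows with the strength of a single constraint", {
  # one pattern whose |lambda| grows over time and is centered to keep the
  # baseline exactly recoverable: check monotone growth in |lambda|
  n <- 200
  set.seed(21)
  b <- rnorm(n, 5, 0.8)
  W <- rnorm(n)
  Q <- qr.Q(qr(cbind(rep(1, n), b, W)))
  g <- Q[, 3]
  lam_t <- c(0, 1, 2, -3)          # zero-mean, |lambda| growing over time
  Y <- matrix(b, n, 4) + outer(g, lam_t)
  dimnames(Y) <- list(sprintf("g%03d", 1:n), as.character(1:4))
  fit <- suppressWarnings(surprisal_decompose(log_matrix(Y), cv_baseline = 0.5))
  d <- entropy_deficiency(fit)
  expect_true(all(diff(d$deficiency) > -1e-12))
  expect_gt(d$deficiency[4], d$deficiency[2])
})

test_that("rescaling all levels moves only the baseline term", {
  pl <- planted_log_matrix(n = 220, profiles = list(c(1, 0.5, -0.5, -1),
                                                    c(0.5, -0.5, -0.5, 0.5)))
  fit1 <- suppressWarnings(surprisal_decompose(pl$Y))
  Y2 <- pl$Y$values + log(10)          # levels multiplied by 10
  dimnames(Y2) <- dimnames(pl$Y$values)
  fit2 <- suppressWarnings(surprisal_decompose(log_matrix(Y2)))
  expect_lt(max(abs(fit1$lambda[-1, ] - fit2$lambda[-1, ])), 1e-8)
  expect_gt(mean(fit2$lambda[1, ] - fit1$lambda[1, ]), 0)
})

test_that("gene universe below the time-point count is refused", {
  Y <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("1", "2", "3")))
  expect_error(surprisal_decompose(log_matrix(Y)), "fewer genes")
})
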