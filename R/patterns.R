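#' Rank the time-varying transcription patterns by importance
#'
#' Importance is the size of the time-independent magnitude `omega_a`; the
#' baseline pattern is excluded. `alpha = 1` is the dominant time-varying
#' pattern, and consecutive terms of the expansion contribute decreasingly.
#'
#' @param d A `surprisal_fit`.
#' @return A tibble with one row per time-varying pattern: `rank`, `pattern`
#'   (0-based index in the fit), `omega`, `lambda` and `P` (list columns
#'   holding the named per-time profiles).
#' @export
rank_patterns <- function(d) {
  stopifnot(inherits(d, "surprisal_fit"))
  idx <- varying_order(d)
  om <- d$omega[idx]
  if (length(om) >= 2L) {
    # ties among patterns that actually carry weight (zero tails are vacuous)
    gap <- diff(-om) / max(om[1], .Machine$double.xmin)
    live <- om[-length(om)] > 1e-10 * max(d$omega)
    if (any(gap < 1e-8 & live)) {
      warning("tied pattern importances: ranking order among the tied ",
              "patterns is conventional, not unique", call. = FALSE)
    }
  }
  tibble::tibble(
    rank = seq_along(idx),
    pattern = idx - 1L,
    omega = unname(om),
    lambda = lapply(idx, function(i) d$lambda[i, ]),
    P = lapply(idx, function(i) d$P[i, ])
  )
}

#' Detect sign inversions of a pattern's weight along the trajectory
#'
#' An inversion is a sign change of `lambda_a(t)` between consecutive time
#' points: genes highly expressed under the pattern before the flip become
#' under-expressed after it, and vice versa. Because a fitted weight of
#' "zero" is never exactly zero, time points whose `|lambda|` falls below a
#' noise floor are ignored; a sign change across one or more ignored points
#' is still reported (spanning the near-zero stretch) and flagged.
#'
#' @param d A `surprisal_fit`.
#' @param alpha Pattern index (0-based); must be time-varying.
#' @param noise_floor Magnitude below which a weight is treated as noise;
#'   default 5% of the pattern's maximum `|lambda|`.
#' @return A tibble of events: `pattern`, `time_before`, `time_after`,
#'   `lambda_before`, `lambda_after`, `magnitude`
#'   (`|lambda_after - lambda_before|`), and `spans_below_floor` (`TRUE` when
#'   the two endpoints are not adjacent time points).
#' @export
detect_inversions <- function(d, alpha, noise_floor = NULL) {
  stopifnot(inherits(d, "surprisal_fit"))
  row <- pattern_row(d, alpha)
  if (!is.na(d$alpha0) && as.integer(alpha) == d$alpha0) {
    stop("pattern ", alpha, " is the time-invariant baseline; inversion ",
         "detection applies to time-varying patterns", call. = FALSE)
  }
  lam <- d$lambda[row, ]
  if (is.null(noise_floor)) noise_floor <- 0.05 * max(abs(lam))
  keep <- which(abs(lam) > noise_floor)
  empty <- tibble::tibble(
    pattern = integer(), time_before = character(), time_after = character(),
    lambda_before = double(), lambda_after = double(), magnitude = double(),
    spans_below_floor = logical()
  )
  if (length(keep) < 2L) return(empty)
  i <- keep[-length(keep)]
  j <- keep[-1L]
  flips <- sign(lam[i]) != sign(lam[j])
  if (!any(flips)) return(empty)
  tibble::tibble(
    pattern = as.integer(alpha),
    time_before = d$time_labels[i[flips]],
    time_after = d$time_labels[j[flips]],
    lambda_before = unname(lam[i[flips]]),
    lambda_after = unname(lam[j[flips]]),
    magnitude = abs(unname(lam[j[flips]] - lam[i[flips]])),
    spans_below_floor = (j[flips] - i[flips]) > 1L
  )
}

#' Select the transcripts driving a pattern between two time points
#'
#' Computes each gene's single-pattern contribution to the change in log
#' expression, `G_ia * (lambda_a(t') - lambda_a(t))`, and keeps genes whose
#' contribution exceeds `threshold` in magnitude (the classic "changed by at
#' least exp(+0.5)" rule corresponds to `threshold = 0.5` on the natural-log
#' scale). Genes with contribution `>= +threshold` are `induced`, those with
#' `<= -threshold` are `reduced`. An optional per-gene p-value gate is applied
#' first: with `p_rule = "ge"` (default) genes pass when `p >= p_cut`,
#' matching the replicate-consistency reading in which passing means no
#' detectable replicate disagreement; `p_rule = "lt"` keeps `p < p_cut`
#' instead (e.g. for differential-expression p-values).
#'
#' @param d A `surprisal_fit`.
#' @param alpha Pattern index (0-based).
#' @param time_from,time_to Time labels `t` and `t'`.
#' @param threshold Positive cutoff on the natural-log scale (default 0.5).
#' @param pvals Optional named per-gene p-values (names = gene ids); genes
#'   missing from `pvals` fail the gate.
#' @param p_cut P-value cutoff for the gate (default 0.05).
#' @param p_rule `"ge"` or `"lt"`, see above.
#' @return A tibble sorted by decreasing contribution: `gene_id`, `pattern`,
#'   `delta_ln`, `direction` (`"induced"`/`"reduced"`).
#' @export
select_contributing_genes <- function(d, alpha, time_from, time_to,
                                      threshold = 0.5, pvals = NULL,
                                      p_cut = 0.05, p_rule = c("ge", "lt")) {
  stopifnot(inherits(d, "surprisal_fit"))
  p_rule <- match.arg(p_rule)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  term <- delta_expression(d, time_from, time_to, alphas = alpha)
  eligible <- rep(TRUE, length(term))
  if (!is.null(pvals)) {
    p <- pvals[d$gene_ids]
    eligible <- !is.na(p) & (if (p_rule == "ge") p >= p_cut else p < p_cut)
  }
  sel <- eligible & abs(term) >= threshold
  out <- tibble::tibble(
    gene_id = d$gene_ids[sel],
    pattern = as.integer(alpha),
    delta_ln = unname(term[sel]),
    direction = dplyr::if_else(term[sel] > 0, "induced", "reduced")
  )
  dplyr::arrange(out, dplyr::desc(.data$delta_ln))
}

#' Match transcription patterns between two trajectories
#'
#' Two decompositions over the same gene universe can be compared by matching
#' their gene-weight columns on absolute cosine similarity: since the columns
#' are unit vectors, the cosine is their dot product. Matching is greedy on
#' `|cosine|` by default; `method = "optimal"` solves the assignment exactly
#' (maximum total `|cosine|`) by dynamic programming over pattern subsets,
#' which is cheap for the small pattern counts involved. The reported relative
#' sign lets profiles from the two fits be overlaid on a common orientation.
#'
#' @param da,db Two `surprisal_fit` objects sharing the same gene ids (same
#'   set and order).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A tibble with one row per matched pair: `pattern_a`, `pattern_b`
#'   (0-based indices), `cosine` (signed), `sign` (+1/-1).
#' @export
align_patterns <- function(da, db, method = c("greedy", "optimal")) {
  stopifnot(inherits(da, "surprisal_fit"), inherits(db, "surprisal_fit"))
  method <- match.arg(method)
  if (!identical(da$gene_ids, db$gene_ids)) {
    stop("the two decompositions cover different gene universes; subset both ",
         "inputs to the intersection (in the same order) and refit",
         call. = FALSE)
  }
  C <- crossprod(da$G, db$G)  # cosines: columns of G are unit vectors
  pairs <- if (method == "greedy") greedy_match(abs(C)) else optimal_match(abs(C))
  cosine <- C[cbind(pairs$row, pairs$col)]
  out <- tibble::tibble(
    pattern_a = pairs$row - 1L,
    pattern_b = pairs$col - 1L,
    cosine = cosine,
    sign = ifelse(cosine >= 0, 1, -1)
  )
  dplyr::arrange(out, .data$pattern_a)
}

greedy_match <- function(S) {
  n <- min(dim(S))
  rows <- integer(n); cols <- integer(n)
  for (k in seq_len(n)) {
    ij <- which(S == max(S), arr.ind = TRUE)[1, ]
    rows[k] <- ij[1]; cols[k] <- ij[2]
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  list(row = rows, col = cols)
}

# exact assignment by DP over column subsets (bitmask); rows <= cols assumed
# square here since both fits have one pattern per time point
optimal_match <- function(S) {
  n <- nrow(S); m <- ncol(S)
  stopifnot(n <= m, m <= 20)
  nmask <- bitwShiftL(1L, m)
  best <- rep(-Inf, nmask); best[1L] <- 0
  choice <- matrix(0L, nrow = n, ncol = nmask)
  # process rows in order; state = set of used columns
  for (r in seq_len(n)) {
    nxt <- rep(-Inf, nmask)
    for (mask in 0:(nmask - 1L)) {
      if (best[mask + 1L] == -Inf) next
      if (sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) > 0) != r - 1L) next
      for (c in seq_len(m)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(mask, bit) > 0) next
        v <- best[mask + 1L] + S[r, c]
        if (v > nxt[bitwOr(mask, bit) + 1L]) {
          nxt[bitwOr(mask, bit) + 1L] <- v
          choice[r, bitwOr(mask, bit) + 1L] <- c
        }
      }
    }
    best <- nxt
  }
  # backtrack from the best full-ish state
  full_states <- which(best > -Inf) - 1L
  mask <- full_states[which.max(best[full_states + 1L])]
  rows <- integer(n); cols <- integer(n)
  for (r in rev(seq_len(n))) {
    c <- choice[r, mask + 1L]
    rows[r] <- r; cols[r] <- c
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, c - 1L)))
  }
  list(row = rows, col = cols)
}
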