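#' Keep genes detected in all replicates of at least one time point
#'
#' Reproduces the Affymetrix-style detection filter: a gene is analyzable only
#' if it carries a "present" call in every replicate of at least one time
#' point (for duplicates: present in both duplicates of at least one sample).
#'
#' @param m An `expr_mat` carrying present flags.
#' @return The filtered `expr_mat`; the decision is recorded in
#'   [filter_report()].
#' @export
filter_present_calls <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (is.null(m$present)) {
    stop("no present/absent flags on this matrix; either load a call-flag ",
         "table or skip this filter explicitly", call. = FALSE)
  }
  keep <- rep(FALSE, length(m$gene_ids))
  for (label in m$time_labels) {
    cols <- samples_for_label(m, label)
    keep <- keep | matrixStats_all(m$present[, cols, drop = FALSE])
  }
  keep_genes(m, keep, step = "present_call")
}

matrixStats_all <- function(x) rowSums(x) == ncol(x)

#' Remove genes whose duplicate measurements disagree systematically
#'
#' For each gene, the replicate-1 series (across time points) is compared
#' against the replicate-2 series by a paired t-test. A gene is retained when
#' the test does *not* reject equality at level `alpha`, i.e. when there is no
#' detectable systematic disagreement between its duplicates. Set
#' `invert = TRUE` to keep only genes that *do* reject (the opposite reading
#' of a "variation below 0.05" rule).
#'
#' Degenerate difference series are resolved without calling [stats::t.test()]:
#' identical replicates (all differences zero) are retained (p = 1); a
#' constant non-zero offset between replicates (zero-variance differences) is
#' treated as maximal evidence of disagreement and removed (p = 0).
#'
#' @param m An `expr_mat` with exactly 2 replicates per time point and at
#'   least 2 time points.
#' @param alpha Significance level of the paired t-test (default 0.05).
#' @param invert Flip the retention rule.
#' @return The filtered `expr_mat`, with per-gene p-values in
#'   `attr(, "replicate_pvalues")` (named vector over the *input* genes) and
#'   the decision recorded in [filter_report()].
#' @export
replicate_consistency_filter <- function(m, alpha = 0.05, invert = FALSE) {
  stopifnot(inherits(m, "expr_mat"))
  if (n_replicates(m) != 2L) {
    stop("replicate consistency filter requires exactly 2 replicates per ",
         "time point", call. = FALSE)
  }
  if (length(m$time_labels) < 2L) {
    stop("paired t-test undefined with fewer than 2 time points", call. = FALSE)
  }
  rep1 <- vapply(m$time_labels, function(l) samples_for_label(m, l)[1], "")
  rep2 <- vapply(m$time_labels, function(l) samples_for_label(m, l)[2], "")
  d <- m$levels[, rep1, drop = FALSE] - m$levels[, rep2, drop = FALSE]
  pvals <- apply(d, 1L, paired_t_pvalue)
  names(pvals) <- m$gene_ids
  keep <- if (invert) pvals < alpha else pvals >= alpha
  out <- keep_genes(m, keep, step = "replicate_consistency")
  attr(out, "replicate_pvalues") <- pvals
  out
}

paired_t_pvalue <- function(d) {
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)  # constant non-zero offset: t is infinite
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

#' Average replicate measurements on the linear scale
#'
#' Collapses the replicate columns of each time point to their arithmetic
#' mean (of linear-scale levels, before any log transform), yielding one
#' column per time label. Present flags do not survive averaging.
#'
#' @param m An `expr_mat`.
#' @return An `expr_mat` with a single column per time label, named by the
#'   label itself.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  avg <- vapply(m$time_labels, function(label) {
    rowMeans(m$levels[, samples_for_label(m, label), drop = FALSE])
  }, numeric(length(m$gene_ids)))
  avg <- matrix(avg, nrow = length(m$gene_ids),
                dimnames = list(m$gene_ids, m$time_labels))
  out <- expression_matrix(
    avg,
    samples = tibble::tibble(sample = m$time_labels,
                             time_label = m$time_labels,
                             replicate = 1L)
  )
  attr(out, "filter_report") <- filter_report(m)
  attr(out, "replicate_pvalues") <- attr(m, "replicate_pvalues")
  out
}
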