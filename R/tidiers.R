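#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a surprisal decomposition
#'
#' @param x A `surprisal_fit`.
#' @param matrix Which component to tidy: `"lambda"` (default; one row per
#'   pattern/time with `lambda`, `omega`, `P`), `"G"` (one row per
#'   gene/pattern weight), or `"P"` (fractional profiles only).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy surprisal_fit
#' @export
tidy.surprisal_fit <- function(x, matrix = c("lambda", "G", "P"), ...) {
  matrix <- match.arg(matrix)
  A <- length(x$omega)
  pat <- seq_len(A) - 1L
  if (matrix == "G") {
    return(tibble::tibble(
      gene_id = rep(x$gene_ids, times = A),
      pattern = rep(pat, each = nrow(x$G)),
      weight = as.vector(x$G)
    ))
  }
  out <- tibble::tibble(
    pattern = rep(pat, times = ncol(x$lambda)),
    time_label = rep(x$time_labels, each = A),
    lambda = as.vector(x$lambda),
    omega = rep(unname(x$omega), times = ncol(x$lambda)),
    P = as.vector(x$P)
  )
  if (matrix == "P") out <- out[, c("pattern", "time_label", "P")]
  out
}

#' One-row summary of a surprisal decomposition
#'
#' @param x A `surprisal_fit`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_times`, `n_patterns`, `alpha0`,
#'   `lambda0_cv` (NA when no baseline), `omega_max`,
#'   `dominant_varying_share` (omega of the top time-varying pattern over the
#'   total time-varying omega mass).
#' @method glance surprisal_fit
#' @export
glance.surprisal_fit <- function(x, ...) {
  varying <- varying_order(x)
  cv <- if (is.na(x$alpha0)) NA_real_ else check_lambda0_constancy(x)$cv
  tibble::tibble(
    n_genes = nrow(x$G),
    n_times = length(x$time_labels),
    n_patterns = length(x$omega),
    alpha0 = x$alpha0,
    lambda0_cv = cv,
    omega_max = max(x$omega),
    dominant_varying_share = if (length(varying))
      x$omega[varying[1]] / sum(x$omega[varying]) else NA_real_
  )
}

#' Per-gene fitted values from a truncated reconstruction
#'
#' @param x A `surprisal_fit`.
#' @param k Number of time-varying patterns used (default all).
#' @param ... Unused.
#' @return A tibble with `gene_id`, `time_label`, `log_level` (measured) and
#'   `.fitted` (reconstructed with `k` patterns).
#' @method augment surprisal_fit
#' @export
augment.surprisal_fit <- function(x, k = length(x$omega) - 1L, ...) {
  rec <- reconstruct(x, k)
  out <- tidy.log_mat(log_matrix(x$Y, x$floor_used))
  out$.fitted <- as.vector(rec$values)
  out
}
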