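#' Plot Lagrange-multiplier time profiles
#'
#' Shows `lambda_a(t)` against the trajectory's time points for the most
#' important time-varying patterns, the standard way to read off when a
#' pattern matters and where its weight inverts sign.
#'
#' @param fit A `surprisal_fit`.
#' @param n_patterns How many top time-varying patterns to draw (default 3).
#' @param include_baseline Also draw `lambda_0` (default `FALSE`; it dwarfs
#'   the varying patterns).
#' @return A ggplot object.
#' @export
plot_lambda_profiles <- function(fit, n_patterns = 3, include_baseline = FALSE) {
  stopifnot(inherits(fit, "surprisal_fit"))
  keep <- utils::head(varying_order(fit), n_patterns) - 1L
  if (include_baseline && !is.na(fit$alpha0)) keep <- c(fit$alpha0, keep)
  df <- tidy.surprisal_fit(fit)
  df <- df[df$pattern %in% keep, ]
  df$time_label <- factor(df$time_label, levels = fit$time_labels)
  df$pattern <- factor(df$pattern)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_label, y = .data$lambda,
                                   colour = .data$pattern,
                                   group = .data$pattern)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time point", y = expression(lambda[alpha](t)),
                  colour = "pattern") +
    ggplot2::theme_minimal()
}

#' Scatter of reconstructed vs. measured log expression
#'
#' Plots the `k`-pattern reconstruction of every gene's log level at one time
#' point against the measured value; with all patterns the points lie on the
#' identity line, and one or two dominant patterns already hug it.
#'
#' @param fit A `surprisal_fit`.
#' @param k Number of time-varying patterns in the reconstruction.
#' @param time Time label (default the first).
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(fit, k = 1, time = NULL) {
  stopifnot(inherits(fit, "surprisal_fit"))
  if (is.null(time)) time <- fit$time_labels[1]
  j <- time_col(fit, time)
  rec <- reconstruct(fit, k)
  df <- tibble::tibble(measured = fit$Y[, j], computed = rec$values[, j])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$computed)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = "measured ln X", y = sprintf("reconstructed ln X (k = %d)", k),
      subtitle = sprintf("time %s, R^2 = %.4f", time,
                         attr(rec, "r_squared")[j])
    ) +
    ggplot2::theme_minimal()
}

#' Waterfall of single-pattern expression changes between two time points
#'
#' Orders all genes by their single-pattern change
#' `G_ia * (lambda_a(t') - lambda_a(t))` and plots the sorted values; genes
#' at the two ends are the ones the pattern induces or reduces most, and the
#' flat middle shows the many genes the pattern leaves untouched.
#'
#' @param fit A `surprisal_fit`.
#' @param alpha Pattern index (0-based).
#' @param time_from,time_to Time labels.
#' @param threshold Optional horizontal guide lines at +/- threshold.
#' @return A ggplot object.
#' @export
plot_delta_waterfall <- function(fit, alpha, time_from, time_to,
                                 threshold = 0.5) {
  stopifnot(inherits(fit, "surprisal_fit"))
  d <- sort(delta_expression(fit, time_from, time_to, alphas = alpha))
  df <- tibble::tibble(order = seq_along(d), delta_ln = unname(d))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$delta_ln)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "genes, ordered by increasing change",
                  y = sprintf("pattern-%s term of ln X(%s) - ln X(%s)",
                              alpha, time_to, time_from)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                                 linetype = 3, colour = "grey50")
  }
  p
}

#' Autoplot method for surprisal fits
#'
#' @param object A `surprisal_fit`.
#' @param type `"lambda"` (default), `"reconstruction"`, or `"delta"`.
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @method autoplot surprisal_fit
#' @export
autoplot.surprisal_fit <- function(object,
                                   type = c("lambda", "reconstruction", "delta"),
                                   ...) {
  type <- match.arg(type)
  switch(type,
         lambda = plot_lambda_profiles(object, ...),
         reconstruction = plot_reconstruction(object, ...),
         delta = plot_delta_waterfall(object, ...))
}
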