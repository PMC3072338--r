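#' Construct a log expression matrix
#'
#' The gene-by-time matrix of natural-log expression levels that the
#' decomposition operates on: one column per time label, finite entries only.
#'
#' @param values Numeric matrix (genes x time points) of natural-log levels,
#'   with gene ids as row names and time labels as column names.
#' @param floor_used The positive constant that was substituted for zero
#'   levels before taking logs, or `NA` when none was needed.
#' @return An object of class `log_mat`.
#' @export
log_matrix <- function(values, floor_used = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene ids as row names and time labels as column names",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("log expression matrix must be finite", call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("at least 2 time points are required", call. = FALSE)
  }
  structure(
    list(gene_ids = rownames(values), time_labels = colnames(values),
         values = values, floor_used = floor_used),
    class = "log_mat"
  )
}

#' @export
print.log_mat <- function(x, ...) {
  cat(sprintf("<log_mat> %d genes x %d time points (natural log scale)\n",
              nrow(x$values), ncol(x$values)))
  cat("  time labels:", paste(x$time_labels, collapse = " "), "\n")
  if (!is.na(x$floor_used)) cat("  zero floor used:", x$floor_used, "\n")
  invisible(x)
}

#' @export
dim.log_mat <- function(x) dim(x$values)

#' Natural-log transform of an averaged expression matrix
#'
#' Takes the natural logarithm of each level. Zeros (which have no finite
#' log) are replaced beforehand by a positive floor: `"auto"` uses half the
#' smallest positive level in the matrix, `"strict"` refuses any zero, and a
#' positive number is used as given.
#'
#' @param m An `expr_mat` with one column per time label (run
#'   [average_replicates()] first if needed).
#' @param floor `"auto"` (default), `"strict"`, or a positive number.
#' @return A [log_matrix()].
#' @export
log_transform <- function(m, floor = "auto") {
  stopifnot(inherits(m, "expr_mat"))
  if (n_replicates(m) != 1L) {
    stop("log_transform expects one column per time label; call ",
         "average_replicates() first", call. = FALSE)
  }
  x <- m$levels
  floor_used <- NA_real_
  if (any(x == 0)) {
    if (identical(floor, "strict")) {
      zero_rows <- m$gene_ids[rowSums(x == 0) > 0]
      stop("zero levels present with floor = \"strict\" (e.g. gene '",
           zero_rows[1], "')", call. = FALSE)
    }
    floor_used <- if (identical(floor, "auto")) {
      pos <- x[x > 0]
      if (length(pos) == 0) stop("all levels are zero; no positive floor available",
                                 call. = FALSE)
      min(pos) / 2
    } else {
      stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
      as.numeric(floor)
    }
    x[x == 0] <- floor_used
  }
  log_matrix(log(x), floor_used = floor_used)
}

#' Tidy a log matrix into long format
#'
#' @param x A `log_mat`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `time_label`, `log_level`.
#' @method tidy log_mat
#' @export
tidy.log_mat <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(x$gene_ids, times = ncol(x$values)),
    time_label = rep(x$time_labels, each = nrow(x$values)),
    log_level = as.vector(x$values)
  )
}
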