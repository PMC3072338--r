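#' Construct an expression matrix with replicate structure
#'
#' The basic data container of the package: a gene-by-sample table of
#' non-negative, linear-scale expression levels, together with the mapping
#' from samples to time-point labels and (optionally) per-cell present/absent
#' detection flags. Each time label must carry the same number of replicate
#' samples (duplicates in the original microarray design, but any count works).
#'
#' @param levels Numeric matrix, genes in rows and samples in columns. Row
#'   names are gene identifiers; column names are sample identifiers of the
#'   form `<timeLabel>_<replicateIndex>` unless `samples` is supplied.
#' @param samples Optional data frame with columns `sample`, `time_label`,
#'   `replicate` overriding header-driven inference.
#' @param present Optional logical matrix of the same shape as `levels`
#'   (`TRUE` = detected/"present"), or a character matrix with values in
#'   `P`/`A`/`M` of which only `P` counts as present.
#' @return An object of class `expr_mat`.
#' @export
expression_matrix <- function(levels, samples = NULL, present = NULL) {
  if (!is.matrix(levels) || !is.numeric(levels)) {
    stop("`levels` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  gene_ids <- rownames(levels)
  if (is.null(gene_ids)) {
    stop("`levels` must have gene identifiers as row names", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(levels) || any(!is.finite(levels))) {
    stop("expression levels contain missing or non-finite values", call. = FALSE)
  }
  if (any(levels < 0)) {
    idx <- which(levels < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression level for gene '%s' in sample '%s'",
                 gene_ids[idx[1]], colnames(levels)[idx[2]]), call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- infer_sample_map(colnames(levels))
  } else {
    samples <- tibble::as_tibble(samples)
    stopifnot(all(c("sample", "time_label", "replicate") %in% names(samples)))
    samples$time_label <- as.character(samples$time_label)
    if (!identical(samples$sample, colnames(levels))) {
      samples <- samples[match(colnames(levels), samples$sample), ]
      if (anyNA(samples$sample)) {
        stop("`samples` does not cover all columns of `levels`", call. = FALSE)
      }
    }
  }
  time_labels <- unique(samples$time_label)
  reps_per_label <- table(factor(samples$time_label, levels = time_labels))
  if (length(unique(as.integer(reps_per_label))) != 1L) {
    stop("every time label must have the same replicate count; got: ",
         paste(sprintf("%s=%d", names(reps_per_label), reps_per_label),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(present)) {
    if (is.character(present)) present <- present == "P"
    if (!is.logical(present) || !identical(dim(present), dim(levels))) {
      stop("`present` must be a logical (or P/A/M character) matrix of the ",
           "same shape as `levels`", call. = FALSE)
    }
    dimnames(present) <- dimnames(levels)
  }
  structure(
    list(
      gene_ids = gene_ids,
      levels = levels,
      samples = samples,
      time_labels = time_labels,
      present = present
    ),
    class = "expr_mat"
  )
}

# Header convention: "<timeLabel>_<replicateIndex>"; columns without the
# suffix are treated as single-replicate time points named by the header.
infer_sample_map <- function(sample_names) {
  if (is.null(sample_names)) {
    stop("`levels` must have sample names as column names", call. = FALSE)
  }
  m <- regmatches(sample_names, regexec("^(.*)_([0-9]+)$", sample_names))
  has_rep <- lengths(m) == 3L
  label <- ifelse(has_rep, vapply(m, function(x) x[2], "", USE.NAMES = FALSE),
                  sample_names)
  rep_idx <- ifelse(has_rep,
                    as.integer(vapply(m, function(x) x[3], "", USE.NAMES = FALSE)),
                    1L)
  tibble::tibble(sample = sample_names, time_label = label, replicate = rep_idx)
}

#' @export
print.expr_mat <- function(x, ...) {
  nrep <- n_replicates(x)
  cat(sprintf("<expr_mat> %d genes x %d samples (%d time points, %d replicate%s each)\n",
              length(x$gene_ids), ncol(x$levels), length(x$time_labels),
              nrep, if (nrep == 1) "" else "s"))
  cat("  time labels:", paste(x$time_labels, collapse = " "), "\n")
  cat("  present flags:", if (is.null(x$present)) "none" else "available", "\n")
  rep <- filter_report(x)
  if (nrow(rep)) cat("  filters applied:", paste(rep$step, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$levels)

n_replicates <- function(m) {
  as.integer(sum(m$samples$time_label == m$time_labels[1]))
}

samples_for_label <- function(m, label) {
  m$samples$sample[m$samples$time_label == label]
}

keep_genes <- function(m, keep, step, report = NULL) {
  removed <- m$gene_ids[!keep]
  out <- m
  out$gene_ids <- m$gene_ids[keep]
  out$levels <- m$levels[keep, , drop = FALSE]
  if (!is.null(m$present)) out$present <- m$present[keep, , drop = FALSE]
  entry <- tibble::tibble(
    step = step,
    n_input = length(m$gene_ids),
    n_kept = sum(keep),
    n_removed = sum(!keep),
    removed_gene_ids = list(removed)
  )
  attr(out, "filter_report") <- dplyr::bind_rows(filter_report(m), entry)
  out
}

#' Retrieve the cumulative filter report of an expression matrix
#'
#' Each filtering step ([filter_present_calls()], [replicate_consistency_filter()])
#' appends one row recording how many genes entered, survived, and were removed,
#' plus the removed identifiers.
#'
#' @param m An `expr_mat`.
#' @return A tibble with columns `step`, `n_input`, `n_kept`, `n_removed`,
#'   `removed_gene_ids` (list column).
#' @export
filter_report <- function(m) {
  rep <- attr(m, "filter_report")
  if (is.null(rep)) {
    rep <- tibble::tibble(
      step = character(), n_input = integer(), n_kept = integer(),
      n_removed = integer(), removed_gene_ids = list()
    )
  }
  rep
}

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with one row per gene/sample cell: `gene_id`, `sample`,
#'   `time_label`, `replicate`, `level`, and `present` when flags exist.
#' @method tidy expr_mat
#' @export
tidy.expr_mat <- function(x, ...) {
  out <- tibble::tibble(
    gene_id = rep(x$gene_ids, times = ncol(x$levels)),
    sample = rep(colnames(x$levels), each = nrow(x$levels)),
    level = as.vector(x$levels)
  )
  out <- dplyr::left_join(out, x$samples, by = "sample")
  if (!is.null(x$present)) out$present <- as.vector(x$present)
  out[, c("gene_id", "sample", "time_label", "replicate", "level",
          intersect("present", names(out)))]
}

#' Read an expression table from delimited text
#'
#' Expects a tab- or comma-delimited file whose first column holds gene
#' identifiers and whose remaining column headers name samples as
#' `<timeLabel>_<replicateIndex>` (e.g. `7_1`, `7_2`). An optional parallel
#' call-flag table of identical shape supplies Affymetrix-style detection
#' calls (`P`/`A`/`M`; only `P` counts as present).
#'
#' @param path Path to the expression table.
#' @param call_path Optional path to the call-flag table.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs. comma from
#'   the header line.
#' @return An [expression_matrix()] object.
#' @export
load_expression_table <- function(path, call_path = NULL, delim = NULL) {
  df <- read_delim_checked(path, delim)
  gene_ids <- as.character(df[[1]])
  levels <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(levels)) {
    bad <- names(df)[-1][!vapply(df[-1], is.numeric, TRUE)]
    stop("non-numeric expression column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(levels) <- gene_ids
  present <- NULL
  if (!is.null(call_path)) {
    cf <- read_delim_checked(call_path, delim, coltypes = "character")
    if (!identical(dim(cf), dim(df)) ||
        !identical(as.character(cf[[1]]), gene_ids)) {
      stop("call-flag table does not match the expression table's shape ",
           "and gene order", call. = FALSE)
    }
    present <- as.matrix(cf[, -1, drop = FALSE]) == "P"
    rownames(present) <- gene_ids
  }
  expression_matrix(levels, present = present)
}

# base read.table rather than a fast parser: strtod parsing round-trips
# written doubles bit-for-bit, and ragged rows fail with the line number
read_delim_checked <- function(path, delim = NULL, coltypes = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  n_fields <- length(strsplit(header, delim, fixed = TRUE)[[1]])
  classes <- if (identical(coltypes, "character")) "character"
             else c("character", rep("numeric", n_fields - 1L))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, quote = "",
                      colClasses = classes, check.names = FALSE,
                      comment.char = ""),
    error = function(e) {
      stop("malformed table '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  tibble::as_tibble(df)
}

#' Write an expression matrix (and optional call flags) to TSV
#'
#' Emits the same dialect [load_expression_table()] reads, so a written
#' matrix reloads bit-for-bit on values.
#'
#' @param m An `expr_mat`.
#' @param path Output path for the expression table.
#' @param call_path Optional output path for the call-flag table (written only
#'   when `m` carries present flags).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, call_path = NULL) {
  df <- tibble::as_tibble(m$levels)
  df <- dplyr::bind_cols(tibble::tibble(gene_id = m$gene_ids), df)
  readr::write_tsv(df, path)
  if (!is.null(call_path)) {
    if (is.null(m$present)) stop("matrix has no present flags to write", call. = FALSE)
    cf <- tibble::as_tibble(ifelse(m$present, "P", "A"))
    cf <- dplyr::bind_cols(tibble::tibble(gene_id = m$gene_ids), cf)
    readr::write_tsv(cf, call_path)
  }
  invisible(path)
}
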