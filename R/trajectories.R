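#' Parse a trajectory specification string
#'
#' A trajectory is an ordered sequence of time-point labels describing one
#' experimentally continuous route through a branching design, written as a
#' dash- or comma-separated string such as `"1-5-7-8-10-12"`.
#'
#' @param spec Trajectory string, or a character vector of labels.
#' @param annotation Optional free-text annotation per label (e.g. the
#'   perturbation applied), recycled checks apply.
#' @param successors Optional named list mapping each label to its allowed
#'   successor labels; when given, consecutive pairs are checked against it
#'   (experimental continuity constraint).
#' @return An object of class `trajectory`: list with `name`, `labels`,
#'   `annotation`.
#' @export
parse_trajectory <- function(spec, annotation = NULL, successors = NULL) {
  labels <- if (length(spec) > 1L) as.character(spec)
            else strsplit(spec, "[-,]")[[1]]
  labels <- trimws(labels)
  labels <- labels[nzchar(labels)]
  if (length(labels) < 2L) {
    stop("a trajectory needs at least 2 time-point labels; got '",
         paste(labels, collapse = "-"), "'", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("repeated label '", labels[duplicated(labels)][1],
         "' in trajectory", call. = FALSE)
  }
  if (!is.null(successors)) {
    for (k in seq_len(length(labels) - 1L)) {
      ok <- labels[k + 1L] %in% successors[[labels[k]]]
      if (!isTRUE(ok)) {
        stop("label '", labels[k + 1L], "' is not an allowed successor of '",
             labels[k], "'", call. = FALSE)
      }
    }
  }
  if (!is.null(annotation)) {
    stopifnot(length(annotation) == length(labels))
  }
  structure(
    list(name = paste(labels, collapse = "-"), labels = labels,
         annotation = annotation),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$name, sprintf("(%d stages)\n", length(x$labels)))
  invisible(x)
}

as_trajectory <- function(x) {
  if (inherits(x, "trajectory")) x else parse_trajectory(x)
}

#' Extract the columns of one trajectory from a shared matrix
#'
#' Subsets an expression (or log) matrix to the time points of a trajectory,
#' in trajectory order; genes are untouched. For replicate-structured
#' matrices all replicate columns of each label are taken.
#'
#' @param m An `expr_mat` or `log_mat`.
#' @param trajectory A [parse_trajectory()] object or trajectory string.
#' @return A matrix object of the same class as `m`.
#' @export
extract_trajectory <- function(m, trajectory) {
  tr <- as_trajectory(trajectory)
  have <- if (inherits(m, "expr_mat")) m$time_labels else m$time_labels
  missing <- setdiff(tr$labels, have)
  if (length(missing)) {
    stop("time label(s) not in the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (inherits(m, "expr_mat")) {
    cols <- unlist(lapply(tr$labels, function(l) samples_for_label(m, l)))
    out <- expression_matrix(
      m$levels[, cols, drop = FALSE],
      samples = m$samples[match(cols, m$samples$sample), ],
      present = if (is.null(m$present)) NULL else m$present[, cols, drop = FALSE]
    )
    attr(out, "filter_report") <- filter_report(m)
    attr(out, "replicate_pvalues") <- attr(m, "replicate_pvalues")
    out
  } else if (inherits(m, "log_mat")) {
    log_matrix(m$values[, tr$labels, drop = FALSE], floor_used = m$floor_used)
  } else {
    stop("`m` must be an expr_mat or log_mat", call. = FALSE)
  }
}

#' Decompose several trajectories of one experiment
#'
#' Runs an independent surprisal decomposition per trajectory on column
#' subsets of a shared (averaged) expression matrix, tabulates the baseline
#' multiplier per trajectory (different routes may legitimately settle on
#' different time-invariant baselines), and aligns every trajectory's
#' patterns to the first trajectory's for cross-route comparison.
#'
#' @param m An `expr_mat`; replicates are averaged first if present.
#' @param trajectories List (or character vector) of trajectory strings or
#'   [parse_trajectory()] objects.
#' @param floor Zero-level floor policy passed to [log_transform()].
#' @param cv_baseline Passed to [surprisal_decompose()].
#' @param align_method Passed to [align_patterns()].
#' @return An object of class `trajectory_suite`: list with `fits` (named
#'   list of `surprisal_fit`), `lambda0` (tibble: trajectory, time_label,
#'   lambda0, cv), `alignment` (tibble of matches against the first
#'   trajectory; zero rows for a single trajectory), `trajectories`.
#' @export
run_trajectory_suite <- function(m, trajectories, floor = "auto",
                                 cv_baseline = 0.2,
                                 align_method = c("greedy", "optimal")) {
  stopifnot(inherits(m, "expr_mat"))
  align_method <- match.arg(align_method)
  trs <- lapply(trajectories, as_trajectory)
  names(trs) <- vapply(trs, function(t) t$name, "")
  if (n_replicates(m) > 1L) m <- average_replicates(m)

  fits <- lapply(trs, function(tr) {
    sub <- extract_trajectory(m, tr)
    surprisal_decompose(log_transform(sub, floor = floor),
                        cv_baseline = cv_baseline)
  })

  lambda0 <- purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.na(f$alpha0)) {
      return(tibble::tibble(trajectory = nm, time_label = character(),
                            lambda0 = double(), cv = double()))
    }
    rep <- check_lambda0_constancy(f)
    tibble::tibble(trajectory = nm, time_label = names(rep$lambda0),
                   lambda0 = unname(rep$lambda0), cv = rep$cv)
  })

  alignment <- tibble::tibble(
    trajectory = character(), pattern_ref = integer(), pattern = integer(),
    cosine = double(), sign = double()
  )
  if (length(fits) > 1L) {
    ref <- fits[[1L]]
    alignment <- purrr::map_dfr(names(fits)[-1L], function(nm) {
      al <- align_patterns(ref, fits[[nm]], method = align_method)
      tibble::tibble(trajectory = nm, pattern_ref = al$pattern_a,
                     pattern = al$pattern_b, cosine = al$cosine,
                     sign = al$sign)
    })
  }

  structure(
    list(fits = fits, lambda0 = lambda0, alignment = alignment,
         trajectories = trs, reference = names(fits)[1L]),
    class = "trajectory_suite"
  )
}

#' @export
print.trajectory_suite <- function(x, ...) {
  cat(sprintf("<trajectory_suite> %d trajectories\n", length(x$fits)))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cv <- if (is.na(f$alpha0)) NA_real_ else check_lambda0_constancy(f)$cv
    cat(sprintf("  %-16s A = %d, lambda0 CV = %s\n", nm, length(f$omega),
                if (is.na(cv)) "n/a" else signif(cv, 3)))
  }
  if (nrow(x$alignment)) {
    cat("  patterns aligned against:", x$reference, "\n")
  }
  invisible(x)
}
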