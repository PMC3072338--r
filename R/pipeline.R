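#' @importFrom rlang .data
NULL

#' Run the full surprisal-analysis pipeline from a configuration
#'
#' Sequences the whole analysis: ingest the expression (and optional
#' call-flag) table, apply the present-call and replicate-consistency
#' filters, average duplicates, log-transform, decompose each configured
#' trajectory, rank patterns, detect weight inversions, select contributing
#' genes between each trajectory's first and last stages, validate baseline
#' constancy, compute the entropy-deficiency series, and align patterns
#' across trajectories. The run is deterministic given the configuration; the
#' configuration (and its MD5 hash) is embedded verbatim in the result and in
#' every written output for provenance.
#'
#' @param config A list, or a path to a YAML/JSON file, with elements:
#'   `input` (expression table path), `calls` (optional call-flag path),
#'   `trajectories` (character vector of route strings), and optionally
#'   `present_filter` (default: `TRUE` when calls are given),
#'   `replicate_filter` (default `TRUE`), `alpha` (t-test level, 0.05),
#'   `floor` ("auto"), `cv_baseline` (0.2), `contribution_threshold` (0.5),
#'   `lambda0_tol` (0.05), `inversion_floor_frac` (0.05), `seed` (recorded),
#'   `output_dir` (optional; write TSV/JSON outputs there).
#' @return An object of class `surprisal_bundle`: list with `config`,
#'   `config_hash`, `filter_report`, `suite` (a [run_trajectory_suite()]
#'   result), `rankings`, `inversions`, `gene_lists`, `lambda0`, `entropy`
#'   tibbles, and `output_files` (paths written, if any).
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  hash <- config_hash(config)
  out_dir <- config$output_dir
  written <- character()
  cleanup <- function() if (length(written)) unlink(written)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  m <- stage("ingest", load_expression_table(config$input, config$calls))

  do_present <- config$present_filter %||% !is.null(config$calls)
  if (isTRUE(do_present)) m <- stage("present_filter", filter_present_calls(m))
  if (isTRUE(config$replicate_filter %||% TRUE) && n_replicates(m) == 2L) {
    m <- stage("replicate_filter",
               replicate_consistency_filter(m, alpha = config$alpha %||% 0.05))
  }
  m <- stage("average", average_replicates(m))

  suite <- stage("trajectories", run_trajectory_suite(
    m, as.list(config$trajectories),
    floor = config$floor %||% "auto",
    cv_baseline = config$cv_baseline %||% 0.2
  ))

  thr <- config$contribution_threshold %||% 0.5
  floor_frac <- config$inversion_floor_frac %||% 0.05
  lam0_tol <- config$lambda0_tol %||% 0.05

  per_traj <- stage("patterns", purrr::map(names(suite$fits), function(nm) {
    f <- suite$fits[[nm]]
    ranking <- rank_patterns(f)
    inv <- purrr::map_dfr(ranking$pattern, function(a) {
      detect_inversions(f, a,
                        noise_floor = floor_frac * max(abs(f$lambda[a + 1L, ])))
    })
    ends <- c(f$time_labels[1], f$time_labels[length(f$time_labels)])
    genes <- purrr::map_dfr(ranking$pattern, function(a) {
      select_contributing_genes(f, a, ends[1], ends[2], threshold = thr,
                                pvals = attr(m, "replicate_pvalues"))
    })
    lam0 <- if (!is.na(f$alpha0)) check_lambda0_constancy(f, tol_cv = lam0_tol)
            else NULL
    ent <- if (!is.na(f$alpha0)) entropy_deficiency(f) else
      tibble::tibble(time_label = character(), deficiency = double())
    list(name = nm, ranking = ranking, inversions = inv, genes = genes,
         lambda0 = lam0, entropy = ent)
  }))

  add_traj <- function(field) {
    purrr::map_dfr(per_traj, function(p) {
      df <- p[[field]]
      if (nrow(df)) dplyr::bind_cols(tibble::tibble(trajectory = p$name), df)
      else df
    })
  }
  rankings <- add_traj("ranking")
  inversions <- add_traj("inversions")
  gene_lists <- add_traj("genes")
  entropy <- add_traj("entropy")
  lambda0 <- purrr::map_dfr(per_traj, function(p) {
    if (is.null(p$lambda0)) return(tibble::tibble())
    tibble::tibble(trajectory = p$name, cv = p$lambda0$cv,
                   tol_cv = p$lambda0$tol_cv, passed = p$lambda0$passed)
  })

  bundle <- structure(
    list(config = config, config_hash = hash,
         filter_report = filter_report(m), suite = suite,
         rankings = rankings, inversions = inversions,
         gene_lists = gene_lists, lambda0 = lambda0, entropy = entropy,
         output_files = character()),
    class = "surprisal_bundle"
  )

  if (!is.null(out_dir)) {
    written <- stage("write", write_bundle(bundle, out_dir))
    bundle$output_files <- written
  }
  bundle
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$input)) stop("config needs an `input` path", call. = FALSE)
  if (is.null(config$trajectories)) {
    stop("config needs a `trajectories` list", call. = FALSE)
  }
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- list(config = bundle$config, config_hash = bundle$config_hash)
  written <- character()
  wjson <- function(x, name) {
    path <- file.path(dir, name)
    jsonlite::write_json(c(provenance["config_hash"], x), path,
                         auto_unbox = TRUE, digits = I(15), pretty = TRUE)
    written <<- c(written, path)
  }
  wtsv <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_tsv(df, path)
    written <<- c(written, path)
  }
  path <- file.path(dir, "config.json")
  jsonlite::write_json(provenance, path, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, path)

  fr <- bundle$filter_report
  fr$removed_gene_ids <- NULL
  wjson(list(filter_report = fr), "filter_report.json")

  for (nm in names(bundle$suite$fits)) {
    f <- bundle$suite$fits[[nm]]
    tag <- gsub("[^0-9A-Za-z]+", "_", nm)
    wtsv(dplyr::bind_cols(tibble::tibble(gene_id = f$gene_ids),
                          tibble::as_tibble(f$G)),
         sprintf("G_%s.tsv", tag))
    wtsv(dplyr::bind_cols(tibble::tibble(pattern = rownames(f$lambda)),
                          tibble::as_tibble(f$lambda)),
         sprintf("lambda_%s.tsv", tag))
    wjson(list(omega = as.list(f$omega),
               P = apply(f$P, 1L, identity, simplify = FALSE),
               alpha0 = f$alpha0),
          sprintf("omega_P_%s.json", tag))
  }
  if (nrow(bundle$gene_lists)) {
    wtsv(bundle$gene_lists, "contributing_genes.tsv")
  }
  wjson(list(inversions = bundle$inversions), "inversions.json")
  wjson(list(lambda0 = bundle$lambda0,
             lambda0_per_time = bundle$suite$lambda0), "lambda0_report.json")
  wjson(list(entropy_deficiency = bundle$entropy), "entropy.json")
  wjson(list(alignment = bundle$suite$alignment), "alignment.json")
  written
}

#' @export
print.surprisal_bundle <- function(x, ...) {
  cat("<surprisal_bundle>\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  trajectories:", paste(names(x$suite$fits), collapse = ", "), "\n")
  cat(sprintf("  inversions: %d; contributing-gene rows: %d\n",
              nrow(x$inversions), nrow(x$gene_lists)))
  if (length(x$output_files)) {
    cat("  wrote", length(x$output_files), "files\n")
  }
  invisible(x)
}

#' Write diagnostic plots for a pipeline run
#'
#' Produces, per trajectory: the lambda-vs-time profile plot, the
#' reconstructed-vs-measured scatter at a chosen truncation `k`, and the
#' sorted single-pattern change ("waterfall") between the trajectory's first
#' and last stages for its dominant time-varying pattern. Plots are
#' diagnostics; all quantitative results live in the numeric outputs.
#'
#' @param bundle A `surprisal_bundle`.
#' @param dir Output directory.
#' @param k Number of time-varying patterns in the scatter reconstruction.
#' @param device Plot file format (default `"png"`).
#' @return Character vector of the files written, invisibly.
#' @export
render_diagnostics <- function(bundle, dir, k = 1, device = "png") {
  stopifnot(inherits(bundle, "surprisal_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  save_plot <- function(p, name) {
    path <- file.path(dir, paste0(name, ".", device))
    suppressMessages(ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120))
    files <<- c(files, path)
  }
  for (nm in names(bundle$suite$fits)) {
    f <- bundle$suite$fits[[nm]]
    tag <- gsub("[^0-9A-Za-z]+", "_", nm)
    save_plot(plot_lambda_profiles(f), paste0("lambda_", tag))
    save_plot(plot_reconstruction(f, k = min(k, length(f$omega) - 1L),
                                  time = f$time_labels[length(f$time_labels)]),
              paste0("scatter_", tag))
    dom <- varying_order(f)[1] - 1L
    save_plot(plot_delta_waterfall(f, dom, f$time_labels[1],
                                   f$time_labels[length(f$time_labels)]),
              paste0("waterfall_", tag))
  }
  invisible(files)
}
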