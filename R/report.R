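#' Assemble a run configuration
#'
#' Inputs may be in-memory objects or file paths (tree as Newick; matrix,
#' centromeres and breakpoints as TSV). `NULL` inputs fall back to the
#' packaged study fixture.
#'
#' @param tree A `phylo` object or Newick file path.
#' @param matrix Character matrix tibble or TSV path (taxa rows, segment
#'   columns, `"?"` for missing).
#' @param centromeres Long centromere tibble or TSV path.
#' @param breakpoints Breakpoint tibble or TSV path.
#' @param threshold Call threshold, in `(0.5, 1]`.
#' @param alpha Significance level, in `(0, 1)`.
#' @param seed Integer seed used by every stochastic step.
#' @param out_dir Optional output directory for TSV reports.
#' @param holm If `TRUE`, add Holm-adjusted p-values to the screen (off by
#'   default; the primary report uses raw p-values).
#' @return A `run_config` list.
#' @export
run_config <- function(tree = NULL, matrix = NULL, centromeres = NULL,
                       breakpoints = NULL, threshold = 0.75, alpha = 0.05,
                       seed = 1L, out_dir = NULL, holm = FALSE) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  fx <- NULL
  need_fixture <- is.null(tree) || is.null(matrix) || is.null(centromeres) ||
    is.null(breakpoints)
  if (need_fixture) fx <- mus_study_fixture()
  load_tbl <- function(x, default, int_cols = character()) {
    if (is.null(x)) return(default)
    if (is.character(x)) {
      x <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             .default = readr::col_character()))
    }
    for (cc in intersect(int_cols, names(x))) x[[cc]] <- as.integer(x[[cc]])
    x
  }
  if (is.null(tree)) tree <- fx$tree
  if (is.character(tree)) tree <- parse_newick(file = tree)
  matrix <- load_tbl(matrix, fx$matrix)
  centromeres <- load_tbl(centromeres, fx$centromeres, "centromere")
  breakpoints <- load_tbl(breakpoints, fx$breakpoints, "centromere_context")
  mismatch <- union(setdiff(tree$tip.label, matrix$taxon),
                    setdiff(matrix$taxon, tree$tip.label))
  if (length(mismatch)) {
    stop("taxon mismatch between tree and matrix: ",
         paste(mismatch, collapse = ", "), call. = FALSE)
  }
  structure(list(tree = tree, matrix = matrix, centromeres = centromeres,
                 breakpoints = breakpoints, threshold = threshold,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
                 holm = holm),
            class = "run_config")
}

write_report <- function(tbl, config, file) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tbl, file.path(config$out_dir, file))
  }
  invisible(tbl)
}

#' Ancestral-state reconstruction over all segments
#'
#' Fits the three-state ARD model for every segment with at least one
#' observed cluster, computes marginal node probabilities, applies the call
#' threshold and derives insertion/deletion events.
#'
#' @param config A [run_config()].
#' @param n_restarts Random restarts per segment fit.
#' @return A list: `tables` (named list of called `ancestral_table`s),
#'   `events` (tibble over all segments), `event_summary` (deep/terminal
#'   counts by type). TSVs are written when the config has an `out_dir`.
#' @export
cmd_ace <- function(config, n_restarts = 5L) {
  stopifnot(inherits(config, "run_config"))
  segs <- reconstructable_segments(config$matrix)
  message("reconstructing ", length(segs), " segments (threshold ",
          config$threshold, ")")
  tables <- list()
  events <- list()
  for (s in segs) {
    tips <- matrix_tip_data(config$matrix, s)
    fit <- fit_ard(config$tree, tips, n_restarts = n_restarts,
                   seed = config$seed)
    if (!fit$convergence) message("segment ", s, ": optimizer not converged")
    tab <- classify_states(marginal_probs(fit), threshold = config$threshold)
    tables[[s]] <- tab
    ev <- call_events(config$tree, tab)
    if (nrow(ev)) events[[s]] <- dplyr::mutate(ev, segment = s, .before = 1)
    write_report(tab, config, paste0("ancestral_", s, ".tsv"))
  }
  events <- dplyr::bind_rows(events)
  event_summary <- if (nrow(events)) {
    dplyr::count(events, .data$type, .data$depth_class, name = "n")
  } else {
    tibble::tibble(type = character(), depth_class = character(),
                   n = integer())
  }
  write_report(events, config, "events.tsv")
  write_report(event_summary, config, "event_summary.tsv")
  list(tables = tables, events = events, event_summary = event_summary)
}

#' Correlated-evolution screen report
#'
#' Runs [run_all_segments()] under the configuration and reports the
#' per-segment likelihood-ratio tests (raw p-values, as the primary report;
#' Holm adjustment optional).
#'
#' @param config A [run_config()].
#' @param n_restarts Random restarts per model fit.
#' @return A `pagel_screen` tibble (written to `pagel_screen.tsv` when an
#'   `out_dir` is set).
#' @export
cmd_pagel <- function(config, n_restarts = 2L) {
  stopifnot(inherits(config, "run_config"))
  screen <- run_all_segments(config$tree, config$matrix, config$centromeres,
                             alpha = config$alpha, n_restarts = n_restarts,
                             seed = config$seed)
  if (isTRUE(config$holm)) {
    screen$p_holm <- stats::p.adjust(screen$p_value, method = "holm")
  }
  message(attr(screen, "n_significant"), " of ", nrow(screen),
          " segments significant at alpha = ", config$alpha)
  write_report(screen, config, "pagel_screen.tsv")
  screen
}

#' Breakpoint co-occurrence report
#'
#' @param config A [run_config()].
#' @return A list with `classifications` and `summary` (both written as TSV
#'   when an `out_dir` is set).
#' @export
cmd_cooccur <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cls <- classify_breakpoints(config$breakpoints,
                              centromeres = config$centromeres)
  smry <- summarize_cooccurrence(cls)
  write_report(cls, config, "breakpoint_classification.tsv")
  write_report(smry, config, "cooccurrence_summary.tsv")
  list(classifications = cls, summary = smry)
}
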