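#' Classify breakpoints by cluster/centromere context
#'
#' Each breakpoint is categorised by the state of the rDNA cluster and the
#' centromere on its orthologous segment at the time of the rearrangement
#' (the branch it occurred on): `undetermined` when the cluster call is
#' unknown, `cluster_and_centromere` when both structures were present,
#' `neither` when neither was, and `cluster_only` / `centromere_only` for the
#' remainder. For `cluster_and_centromere` records, the sub-position of the
#' break (`distal_end_of_cluster` or `between_centromere_and_cluster`) and
#' the centromere fate (`lost`, `lost_then_reacquired`, `retained`) are
#' carried through.
#'
#' Context can come from two places: explicit `cluster_context` /
#' `centromere_context` columns on the breakpoint table (the packaged study
#' fixture transcribes these), or, when absent, a lookup of the threshold
#' call at the breakpoint's branch in per-segment ancestral tables plus a
#' centromere annotation.
#'
#' @param breakpoints Tibble with `breakpoint_id`, `segment`, `class`,
#'   `branch` and optionally the context columns described above.
#' @param calls Optional named list of called `ancestral_table`s, one per
#'   segment; used with `branch_nodes` when context columns are absent.
#' @param branch_nodes Optional integer vector (parallel to `breakpoints`)
#'   of the child node of the branch each breakpoint sits on.
#' @param centromeres Optional long centromere annotation used in the lookup
#'   path (here: presence at the branch is taken from the explicit column).
#' @return A tibble with `breakpoint_id`, `segment`, `class`, `category`,
#'   `sub_position`, `centromere_fate`.
#' @export
classify_breakpoints <- function(breakpoints, calls = NULL,
                                 branch_nodes = NULL, centromeres = NULL) {
  stopifnot(all(c("segment", "class") %in% names(breakpoints)))
  bad <- setdiff(unique(breakpoints$segment), segment_levels())
  if (length(bad)) {
    stop("unknown segment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(breakpoints)
  if (!"cluster_context" %in% names(breakpoints)) {
    if (is.null(calls) || is.null(branch_nodes)) {
      stop("need cluster_context columns or calls + branch_nodes",
           call. = FALSE)
    }
    cl <- character(n)
    for (i in seq_len(n)) {
      tab <- calls[[breakpoints$segment[i]]]
      if (is.null(tab)) stop("no ancestral table for segment ",
                             breakpoints$segment[i], call. = FALSE)
      call_i <- tab$call[tab$node == branch_nodes[i]]
      cl[i] <- if (call_i == "unknown") "unknown"
               else if (call_i == "absent") "absent" else "present"
    }
    breakpoints$cluster_context <- cl
  }
  if (!"centromere_context" %in% names(breakpoints)) {
    stop("breakpoints need a centromere_context column", call. = FALSE)
  }
  category <- dplyr::case_when(
    breakpoints$cluster_context == "unknown" ~ "undetermined",
    breakpoints$cluster_context == "present" &
      breakpoints$centromere_context == 1 ~ "cluster_and_centromere",
    breakpoints$cluster_context == "absent" &
      breakpoints$centromere_context == 0 ~ "neither",
    breakpoints$cluster_context == "present" ~ "cluster_only",
    TRUE ~ "centromere_only"
  )
  col_or_na <- function(nm) {
    if (nm %in% names(breakpoints)) {
      as.character(breakpoints[[nm]])
    } else {
      rep(NA_character_, n)
    }
  }
  tibble::tibble(
    breakpoint_id = if ("breakpoint_id" %in% names(breakpoints)) {
      breakpoints$breakpoint_id
    } else {
      sprintf("bp%02d", seq_len(n))
    },
    segment = breakpoints$segment,
    class = breakpoints$class,
    category = category,
    sub_position = ifelse(category == "cluster_and_centromere",
                          col_or_na("sub_position"), NA),
    centromere_fate = ifelse(category == "cluster_and_centromere",
                             col_or_na("centromere_fate"), NA)
  )
}

#' Co-occurrence summary of breakpoints with clusters and centromeres
#'
#' Counts the classification categories and reports the flanking percentage:
#' `100 * n_both / (total - n_undetermined)` — the share of breakpoints with
#' a determinable cluster state that fell on either side of a cluster (all of
#' which also carried a centromere). The percentage is kept unrounded;
#' round only at presentation.
#'
#' @param classifications Output of [classify_breakpoints()].
#' @return A one-row `cooccurrence_summary` tibble: `total`,
#'   `n_undetermined`, `n_neither`, `n_both`, `n_other`, `percent_flanking`
#'   (`NA` when no breakpoint has a determinable state).
#' @export
summarize_cooccurrence <- function(classifications) {
  total <- nrow(classifications)
  n_und <- sum(classifications$category == "undetermined")
  n_nei <- sum(classifications$category == "neither")
  n_both <- sum(classifications$category == "cluster_and_centromere")
  n_other <- total - n_und - n_nei - n_both
  denom <- total - n_und
  out <- tibble::tibble(
    total = total, n_undetermined = n_und, n_neither = n_nei,
    n_both = n_both, n_other = n_other,
    percent_flanking = if (denom > 0) 100 * n_both / denom else NA_real_
  )
  class(out) <- c("cooccurrence_summary", class(out))
  out
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Breakpoint co-occurrence summary\n")
  cat("  total breakpoints:       ", x$total, "\n")
  cat("  undetermined cluster:    ", x$n_undetermined, "\n")
  cat("  neither structure:       ", x$n_neither, "\n")
  cat("  cluster + centromere:    ", x$n_both, "\n")
  cat("  other:                   ", x$n_other, "\n")
  if (is.na(x$percent_flanking)) {
    cat("  percent flanking cluster: not available\n")
  } else {
    cat("  percent flanking cluster:",
        sprintf("%.1f%%", x$percent_flanking), "\n")
  }
  invisible(x)
}
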