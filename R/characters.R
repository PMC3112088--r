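#' Expand Robertsonian metacentric notation into its two arms
#'
#' A centric fusion of ancestral acrocentrics `a` and `b` is written `"a.b"`;
#' a cluster assigned to the metacentric is considered present on both arms.
#'
#' @param label A metacentric label of the form `"a.b"`.
#' @return Character vector of the two arm labels.
#' @examples
#' expand_metacentric("4.13")
#' @export
expand_metacentric <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  if (!grepl("^[0-9]+\\.[0-9]+$", label)) {
    stop("'", label, "' is not metacentric notation 'a.b'", call. = FALSE)
  }
  strsplit(label, ".", fixed = TRUE)[[1]]
}

is_metacentric <- function(label) grepl("^[0-9]+\\.[0-9]+$", label)

#' Encode species karyotypes into the 30-segment character matrix
#'
#' Applies the coding rules of the analysis: a cluster on the proximal region
#' of a segment is state `1`, a distal localisation is state `2`, absence is
#' `0` and missing data `"?"`. A pericentromeric cluster lands on the
#' chromosome's proximal segment, a subtelomeric one on its distal segment.
#' Metacentrics (`"a.b"`) contribute a pericentromeric cluster to both arms.
#' Sex-chromosome entries (`"X"`, `"Y"`) are excluded with a message: the
#' orthologous-segment set is autosomal.
#'
#' @param karyotypes Long tibble: `taxon`, `nomenclature`, `chromosome`,
#'   `position` (`pericentromeric`, `subtelomeric` or `interstitial`).
#' @param map Homology map tibble: `nomenclature`, `chromosome`,
#'   `proximal_segment`, `distal_segment` (NA when the chromosome has no
#'   distal counterpart; unsplit chromosomes map both to the same segment).
#' @param missing_cells Optional tibble (`taxon`, `segment`) of cells to code
#'   `"?"` (undetermined homology).
#' @param interstitial_state State used for interstitial clusters: `1`
#'   (proximal side, the default, as only proximal/distal states exist) or
#'   `2`.
#' @return A tibble with a `taxon` column followed by the 30 segment columns,
#'   cells in `c("0","1","2","?")`.
#' @export
encode_matrix <- function(karyotypes, map, missing_cells = NULL,
                          interstitial_state = 1L) {
  stopifnot(all(c("taxon", "nomenclature", "chromosome", "position") %in%
                  names(karyotypes)))
  stopifnot(interstitial_state %in% 1:2)
  segs <- segment_levels()
  taxa <- unique(karyotypes$taxon)
  m <- matrix("0", length(taxa), length(segs),
              dimnames = list(taxa, segs))
  filled_by <- matrix("", length(taxa), length(segs),
                      dimnames = list(taxa, segs))
  assign_state <- function(taxon, segment, state, src) {
    if (!segment %in% segs) {
      stop("unknown segment '", segment, "' from ", src, call. = FALSE)
    }
    prev <- m[taxon, segment]
    if (prev != "0" && prev != state) {
      stop("conflicting states for (", taxon, ", ", segment, "): ",
           prev, " from ", filled_by[taxon, segment], " vs ", state,
           " from ", src, call. = FALSE)
    }
    m[taxon, segment] <<- state
    filled_by[taxon, segment] <<- src
  }
  for (i in seq_len(nrow(karyotypes))) {
    taxon <- karyotypes$taxon[i]
    nom <- karyotypes$nomenclature[i]
    chr <- as.character(karyotypes$chromosome[i])
    pos <- karyotypes$position[i]
    if (chr %in% c("X", "Y")) {
      message("excluding sex-chromosome cluster for ", taxon,
              " (no autosomal segment)")
      next
    }
    arms <- if (is_metacentric(chr)) expand_metacentric(chr) else chr
    for (arm in arms) {
      hit <- map[map$nomenclature == nom & map$chromosome == arm, ,
                 drop = FALSE]
      if (nrow(hit) != 1) {
        stop("unmappable chromosome '", arm, "' (", nom,
             " nomenclature) for ", taxon, call. = FALSE)
      }
      if (pos == "pericentromeric" || is_metacentric(chr)) {
        assign_state(taxon, hit$proximal_segment, "1", chr)
      } else if (pos == "subtelomeric") {
        if (is.na(hit$distal_segment)) {
          stop("no distal segment mapped for chromosome '", arm, "' of ",
               taxon, call. = FALSE)
        }
        assign_state(taxon, hit$distal_segment, "2", chr)
      } else if (pos == "interstitial") {
        if (interstitial_state == 1L) {
          assign_state(taxon, hit$proximal_segment, "1", chr)
        } else {
          assign_state(taxon, hit$distal_segment, "2", chr)
        }
      } else {
        stop("unknown position '", pos, "'", call. = FALSE)
      }
    }
  }
  if (!is.null(missing_cells)) {
    for (i in seq_len(nrow(missing_cells))) {
      m[missing_cells$taxon[i], missing_cells$segment[i]] <- "?"
    }
  }
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(taxon = taxa), out)
  out
}

#' Per-taxon cluster counts
#'
#' Sites are counted as two per cluster-bearing chromosome pair (a signal on
#' at least one homolog marks the pair). Reports the positional breakdown and
#' the across-taxa mean and range of cluster-bearing pairs.
#'
#' @param karyotypes Long karyotype tibble (see [encode_matrix()]).
#' @param ingroup Optional character vector of taxa over which the
#'   mean/range summary is computed (defaults to all taxa).
#' @return A tibble (`taxon`, `n_pairs`, `n_sites`, `n_pericentromeric`,
#'   `n_subtelomeric`, `n_interstitial`) with attribute `overall` holding
#'   `mean_pairs`, `min_pairs`, `max_pairs` over the summary taxa.
#' @export
cluster_summary <- function(karyotypes, ingroup = NULL) {
  out <- karyotypes |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_sites = 2L * dplyr::n(),
      n_pericentromeric = sum(.data$position == "pericentromeric"),
      n_subtelomeric = sum(.data$position == "subtelomeric"),
      n_interstitial = sum(.data$position == "interstitial"),
      .groups = "drop"
    )
  sel <- if (is.null(ingroup)) out else out[out$taxon %in% ingroup, ]
  attr(out, "overall") <- c(
    mean_pairs = mean(sel$n_pairs),
    min_pairs = min(sel$n_pairs),
    max_pairs = max(sel$n_pairs)
  )
  out
}

#' One segment column as tip observation vectors
#'
#' @param matrix Character matrix tibble.
#' @param segment Segment column name.
#' @return A taxa x 3 observation matrix for the pruning likelihood.
#' @export
matrix_tip_data <- function(matrix, segment) {
  stopifnot(segment %in% names(matrix))
  tip_data(setNames(matrix[[segment]], matrix$taxon), k = 3)
}
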