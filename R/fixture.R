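fixture_path <- function(file) {
  system.file("extdata", file, package = "rdnaevol", mustWork = TRUE)
}

read_fixture_tsv <- function(file) {
  readr::read_tsv(fixture_path(file), show_col_types = FALSE,
                  progress = FALSE, col_types = readr::cols(
                    .default = readr::col_character()))
}

#' Packaged study fixture
#'
#' Assembles the packaged 23-taxon dataset: the reference tree (topology with
#' the stated subgeneric order and sister-species constraint; ultrametric
#' branch lengths proportional to clade nesting, synthetic), the 30-segment
#' character matrix encoded from the transcribed karyotype table via
#' [encode_matrix()], the rule-based (synthetic) centromere annotation, and
#' the 42-record breakpoint table with transcribed context columns.
#'
#' @param interstitial_state Passed to [encode_matrix()].
#' @return A list with components `tree` (phylo), `matrix` (tibble, `taxon` +
#'   30 segment columns), `karyotypes`, `taxa`, `map`, `centromeres` (long
#'   tibble with integer `centromere`), `breakpoints`.
#' @export
mus_study_fixture <- function(interstitial_state = 1L) {
  tree <- parse_newick(file = fixture_path("mus_reference_tree.nwk"))
  taxa <- read_fixture_tsv("mus_taxa.tsv")
  kar <- read_fixture_tsv("mus_karyotypes.tsv")
  map <- read_fixture_tsv("mus_homology_map.tsv")
  missing_cells <- read_fixture_tsv("mus_missing_cells.tsv")
  cen <- read_fixture_tsv("mus_centromeres.tsv")
  cen$centromere <- as.integer(cen$centromere)
  bp <- read_fixture_tsv("mus_breakpoints.tsv")
  bp$centromere_context <- as.integer(bp$centromere_context)
  mat <- suppressMessages(encode_matrix(
    kar, map, missing_cells = missing_cells,
    interstitial_state = interstitial_state
  ))
  # keep matrix rows in tree tip order for readability
  mat <- mat[match(tree$tip.label, mat$taxon), , drop = FALSE]
  list(tree = tree, matrix = mat, karyotypes = kar, taxa = taxa, map = map,
       centromeres = cen, breakpoints = bp)
}

#' Segments with at least one observed cluster
#'
#' The ancestral reconstruction runs per segment; a segment on which a
#' cluster was never observed in any taxon carries no signal and is skipped.
#'
#' @param matrix Character matrix tibble.
#' @return Character vector of segment names with any state 1 or 2.
#' @export
reconstructable_segments <- function(matrix) {
  segs <- setdiff(names(matrix), "taxon")
  keep <- vapply(segs, function(s) any(matrix[[s]] %in% c("1", "2")),
                 logical(1))
  segs[keep]
}
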