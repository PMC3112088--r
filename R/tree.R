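#' Parse a rooted Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object, the shared scaffold for every likelihood computation in
#' the package. Multifurcations are accepted; the pruning core handles
#' arbitrary out-degree.
#'
#' @param text A Newick string (must end in `;`), or `NULL` if `file` is given.
#' @param file Path to a Newick file, read when `text` is `NULL`.
#' @param default_length Branch length substituted (with a message) when the
#'   Newick string carries no lengths at all. Keeps likelihoods defined
#'   without silent failure.
#' @return A rooted `phylo` object with non-negative branch lengths and unique
#'   tip labels.
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL, default_length = 1) {
  stopifnot(xor(is.null(text), is.null(file)))
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse failure: malformed tree string", call. = FALSE)
  }
  validate_tree(tree, default_length = default_length)
}

# Shared validation: unique tips, lengths present and non-negative.
validate_tree <- function(tree, default_length = 1) {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    message("tree has no branch lengths; defaulting all to ", default_length)
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    message("tree has missing branch lengths; defaulting them to ",
            default_length)
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tree
}

#' Serialize a tree to a Newick string
#'
#' Round-trip stable: `parse_newick(write_newick(t))` recovers the same
#' topology, labels and branch lengths.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Postorder node sequence
#'
#' Node ids in postorder: every child precedes its parent and the root comes
#' last. Node ids follow ape's convention (tips `1..n`, root `n + 1`).
#'
#' @param tree A `phylo` object.
#' @return Integer vector of node ids, one entry per node, root last.
#' @export
postorder_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  po <- ape::reorder.phylo(tree, "postorder")
  # in postorder edge ordering every edge below a node precedes the node's
  # own edge, so the child column lists all non-root nodes children-first
  c(as.integer(po$edge[, 2]), ape::Ntip(tree) + 1L)
}

# Postorder edge table used by the C++ pruning core.
postorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, lens = po$edge.length,
       root = ape::Ntip(tree) + 1L,
       n_nodes = ape::Ntip(tree) + tree$Nnode)
}

#' Sorted descendant-tip keys for every node
#'
#' Reports key on node ids plus the sorted tuple of descendant tip labels so
#' results are comparable across parsers and tip orderings.
#'
#' @param tree A `phylo` object.
#' @return A tibble with columns `node` and `clade` (comma-separated sorted
#'   descendant tip labels; for tips, the tip label itself).
#' @export
node_clades <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  kids <- lapply(seq_len(n_all), function(i) character(0))
  for (i in seq_len(n_tip)) kids[[i]] <- tree$tip.label[i]
  eo <- postorder_edges(tree)
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; c0 <- eo$edge[e, 2]
    kids[[p]] <- c(kids[[p]], kids[[c0]])
  }
  tibble::tibble(
    node = seq_len(n_all),
    clade = vapply(kids, function(x) paste(sort(x), collapse = ","), "")
  )
}

# Depth (edges from root) per node; used to separate deep vs terminal events.
node_parent <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

#' Tree height (maximum root-to-tip path length)
#' @param tree A `phylo` object.
#' @return A single non-negative number.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}
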