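#' Build a 3-state all-rates-different generator
#'
#' States are ordered `0 = absent`, `1 = pericentromeric`, `2 = distal`. The
#' six instantaneous rates are given in the fixed order
#' `0->1, 0->2, 1->0, 1->2, 2->0, 2->1` (per unit branch length); the diagonal
#' is the negative row sum so every row sums to zero.
#'
#' @param rates Numeric vector of six non-negative rates.
#' @return A 3x3 rate matrix with dimnames `c("0","1","2")`.
#' @examples
#' build_ard_q(rep(1, 6))
#' @export
build_ard_q <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) == 6)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  q <- matrix(0, 3, 3, dimnames = list(c("0", "1", "2"), c("0", "1", "2")))
  q[1, 2] <- rates[1]; q[1, 3] <- rates[2]
  q[2, 1] <- rates[3]; q[2, 3] <- rates[4]
  q[3, 1] <- rates[5]; q[3, 2] <- rates[6]
  diag(q) <- -rowSums(q)
  q
}

ard_rate_names <- function() c("q01", "q02", "q10", "q12", "q20", "q21")

#' Transition probabilities over a branch
#'
#' Computes `P(t) = exp(Q t)` for a continuous-time Markov chain. Rows sum to
#' one and entries lie in `[0, 1]`.
#'
#' @param Q A square rate matrix (rows sum to zero).
#' @param t Non-negative branch length.
#' @return A stochastic matrix of the same dimension as `Q`.
#' @export
transition_probs <- function(Q, t) {
  check_rate_matrix(Q)
  stopifnot(is.numeric(t), length(t) == 1)
  if (t < 0) stop("branch length must be non-negative", call. = FALSE)
  P <- ctmc_pmat_cpp(unname(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

check_rate_matrix <- function(Q) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  offdiag <- Q; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-12 * max(1, max(abs(Q))))) {
    stop("rate-matrix rows must sum to zero", call. = FALSE)
  }
  invisible(Q)
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0` with `sum(pi) = 1`; available as an alternative root
#' prior to the uniform default.
#'
#' @param Q A rate matrix.
#' @return A probability vector of length `nrow(Q)`.
#' @export
stationary_dist <- function(Q) {
  check_rate_matrix(Q)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat / sum(pi_hat)
}

#' Tip observation vectors for a discrete character
#'
#' Encodes one character column as a taxa-by-states 0/1 matrix: a unit vector
#' for an observed state and an all-ones row for missing data (`"?"` or `NA`),
#' which integrates the tip over all states during pruning.
#'
#' @param states Vector of observed states per taxon, either integers in
#'   `0:(k-1)` (possibly as characters) with `"?"`/`NA` for missing, named by
#'   taxon, or a named factor/character of state labels matching `labels`.
#' @param k Number of states.
#' @param labels Optional state labels (defaults to `0:(k-1)` as characters).
#' @return A numeric matrix (taxa x k) with taxon rownames.
#' @export
tip_data <- function(states, k = 3, labels = as.character(seq_len(k) - 1)) {
  stopifnot(!is.null(names(states)), k >= 2, length(labels) == k)
  sv <- as.character(states)
  m <- matrix(0, length(states), k,
              dimnames = list(names(states), labels))
  for (i in seq_along(sv)) {
    if (is.na(sv[i]) || sv[i] == "?") {
      m[i, ] <- 1
    } else {
      j <- match(sv[i], labels)
      if (is.na(j)) stop("unknown state '", sv[i], "' for taxon ",
                         names(states)[i], call. = FALSE)
      m[i, j] <- 1
    }
  }
  m
}

# Align a tip-data matrix with the tree's tip ordering; error on mismatch.
align_tips <- function(tree, tips) {
  stopifnot(is.matrix(tips), !is.null(rownames(tips)))
  missing_in_data <- setdiff(tree$tip.label, rownames(tips))
  extra <- setdiff(rownames(tips), tree$tip.label)
  if (length(missing_in_data) || length(extra)) {
    stop("tip labels do not match tree: missing [",
         paste(missing_in_data, collapse = ", "), "], extra [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  tips[tree$tip.label, , drop = FALSE]
}

#' Root prior
#'
#' @param k Number of states.
#' @param kind `"uniform"` (default), `"stationary"` (needs `Q`), or a numeric
#'   probability vector of length `k`.
#' @param Q Rate matrix, required for `kind = "stationary"`.
#' @return A probability vector of length `k`.
#' @export
root_prior <- function(k, kind = "uniform", Q = NULL) {
  if (is.numeric(kind)) {
    stopifnot(length(kind) == k, all(kind >= 0))
    if (abs(sum(kind) - 1) > 1e-12) stop("prior must sum to 1", call. = FALSE)
    return(kind)
  }
  switch(kind,
    uniform = rep(1 / k, k),
    stationary = stationary_dist(Q),
    stop("unknown prior kind: ", kind, call. = FALSE)
  )
}

#' Pruning log-likelihood of a discrete character on a tree
#'
#' Felsenstein's pruning algorithm with per-node rescaling against underflow.
#' The result is invariant to the order children are visited and to the joint
#' rescaling of branch lengths by `c` and rates by `1/c`.
#'
#' @param tree A `phylo` object.
#' @param tips Tip observation matrix from [tip_data()] (taxa x k, rownames
#'   matching the tree's tip labels exactly).
#' @param Q Rate matrix (k x k).
#' @param prior Root prior vector of length k (default uniform).
#' @return The log-likelihood (a single finite number, or `-Inf` for data of
#'   probability zero).
#' @export
log_likelihood <- function(tree, tips, Q, prior = NULL) {
  check_rate_matrix(Q)
  k <- nrow(Q)
  tips <- align_tips(tree, tips)
  stopifnot(ncol(tips) == k)
  if (is.null(prior)) prior <- root_prior(k)
  eo <- postorder_edges(tree)
  part <- matrix(1, eo$n_nodes, k)
  part[seq_len(nrow(tips)), ] <- tips
  res <- prune_cpp(eo$edge, eo$lens, part, unname(Q), prior, eo$root)
  res$loglik
}

# Marginal (empirical-Bayes) posterior state probabilities at every node,
# via the standard two-pass (pruning up, root-to-tip down) computation.
# Returns an (n_nodes x k) matrix of probabilities summing to one per row.
ctmc_marginals <- function(tree, tips, Q, prior = NULL) {
  check_rate_matrix(Q)
  k <- nrow(Q)
  tips <- align_tips(tree, tips)
  if (is.null(prior)) prior <- root_prior(k)
  eo <- postorder_edges(tree)
  n <- eo$n_nodes
  part <- matrix(1, n, k)
  part[seq_len(nrow(tips)), ] <- tips
  up <- prune_cpp(eo$edge, eo$lens, part, unname(Q), prior, eo$root)
  if (!is.finite(up$loglik)) stop("zero-likelihood data", call. = FALSE)
  part <- up$partials
  P <- edge_pmats_cpp(unname(Q), eo$lens)
  n_edge <- nrow(eo$edge)
  # message flowing up each edge: P_e %*% L(child)
  msgs <- matrix(0, n_edge, k)
  for (e in seq_len(n_edge)) {
    msgs[e, ] <- P[, , e] %*% part[eo$edge[e, 2], ]
  }
  down <- matrix(0, n, k)
  down[eo$root, ] <- prior
  edges_of_parent <- split(seq_len(n_edge), eo$edge[, 1])
  for (e in rev(seq_len(n_edge))) {  # reverse postorder: parents first
    p <- eo$edge[e, 1]; child <- eo$edge[e, 2]
    pre <- down[p, ]
    for (e2 in edges_of_parent[[as.character(p)]]) {
      if (e2 != e) pre <- pre * msgs[e2, ]
    }
    d <- as.numeric(pre %*% P[, , e])
    s <- sum(d)
    down[child, ] <- if (s > 0) d / s else rep(1 / k, k)
  }
  marg <- down * part
  marg[eo$root, ] <- prior * part[eo$root, ]
  rs <- rowSums(marg)
  if (any(rs <= 0)) stop("degenerate marginal at some node", call. = FALSE)
  marg / rs
}
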