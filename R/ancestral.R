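#' Maximum-likelihood fit of the three-state all-rates-different model
#'
#' Fits the six transition rates of the ARD model for one character column by
#' bounded quasi-Newton (`L-BFGS-B` on log-rates) with multiple restarts: the
#' surface can be multimodal for sparse characters, so the fit starts from a
#' moderate default and adds `n_restarts` random starts under a fixed seed.
#' Optimisation runs on a copy of the tree scaled to unit height (rate bounds
#' `[1e-8, 100]` on that scale); reported rates are per unit of the original
#' branch-length scale.
#'
#' @param tree A `phylo` object.
#' @param tips Tip observation matrix from [tip_data()] (taxa x 3), or a
#'   named vector of states `0/1/2/?`.
#' @param prior Root prior (default uniform over the three states).
#' @param n_restarts Number of random restarts added to the default start.
#' @param seed Seed for the restart draws (fit is deterministic given it).
#' @param bounds Rate bounds on the unit-height tree scale.
#' @return An object of class `ard_fit`: MLE `rates` (named), maximised
#'   `loglik`, `convergence` flag, `n_starts` tried, and the fitting context.
#' @export
fit_ard <- function(tree, tips, prior = NULL, n_restarts = 5L, seed = 1L,
                    bounds = c(1e-8, 100)) {
  if (!is.matrix(tips)) tips <- tip_data(tips, k = 3)
  tips <- align_tips(tree, tips)
  if (all(tips == 1)) stop("all tips are missing ('?')", call. = FALSE)
  fit <- fit_ctmc_rates(
    tree, tips, q_builder = build_ard_q, n_rates = 6L, prior = prior,
    n_restarts = n_restarts, seed = seed, bounds = bounds
  )
  structure(
    list(rates = setNames(fit$rates, ard_rate_names()),
         loglik = fit$loglik, convergence = fit$convergence,
         n_starts = fit$n_starts, prior = fit$prior,
         tree = tree, tips = tips),
    class = "ard_fit"
  )
}

#' @export
print.ard_fit <- function(x, ...) {
  cat("Three-state ARD fit\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  cat("  rates:", paste(names(x$rates),
                        format(x$rates, digits = 4), collapse = "  "), "\n")
  cat("  converged:", x$convergence, " (", x$n_starts, "starts )\n")
  invisible(x)
}

# Shared multi-start bounded ML engine for any rate-vector -> Q builder.
# Optimises log-rates on the unit-height-scaled tree; returns rates on the
# caller's original branch-length scale.
fit_ctmc_rates <- function(tree, tips, q_builder, n_rates, prior = NULL,
                           n_restarts = 5L, seed = 1L, bounds = c(1e-8, 100),
                           extra_starts = NULL) {
  h <- tree_height(tree)
  if (h <= 0) stop("tree has zero height", call. = FALSE)
  stree <- tree
  stree$edge.length <- stree$edge.length / h
  k <- ncol(tips)
  if (is.null(prior)) prior <- root_prior(k)
  eo <- postorder_edges(stree)
  part0 <- matrix(1, eo$n_nodes, k)
  part0[seq_len(nrow(tips)), ] <- tips
  nll <- function(logr) {
    Q <- q_builder(exp(logr))
    ll <- prune_cpp(eo$edge, eo$lens, part0, unname(Q), prior, eo$root)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  starts <- list(rep(log(0.5), n_rates))
  if (n_restarts > 0) {
    starts <- c(starts, withr::with_seed(
      derive_seed(seed, "fit_ctmc_rates"),
      replicate(n_restarts, runif(n_rates, log(0.01), log(10)),
                simplify = FALSE)
    ))
  }
  if (!is.null(extra_starts)) starts <- c(extra_starts, starts)
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- tryCatch(
      optim(pmin(pmax(s, lb), ub), nll, method = "L-BFGS-B",
            lower = lb, upper = ub,
            control = list(maxit = 300, factr = 1e8)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("optimizer failed for every start", call. = FALSE)
  list(rates = exp(best$par) / h, loglik = -best$value,
       convergence = conv, n_starts = length(starts), prior = prior,
       par_scaled = exp(best$par))
}

#' Marginal ancestral-state probabilities
#'
#' True marginal (empirical-Bayes) posterior of each state at every node,
#' computed by the two-pass up/down algorithm under the fitted (or supplied)
#' model; each node's probabilities sum to one.
#'
#' @param tree A `phylo` object (defaults to the tree stored in `fit`).
#' @param tips Tip observation matrix (defaults to the one stored in `fit`).
#' @param fit An `ard_fit` object, or a rate matrix `Q`.
#' @param prior Root prior (defaults to the fit's).
#' @return An `ancestral_table` tibble: `node`, `clade` (sorted descendant tip
#'   labels), `is_tip`, and `p_absent`, `p_pericentromeric`, `p_distal`.
#' @export
marginal_probs <- function(fit, tree = NULL, tips = NULL, prior = NULL) {
  if (inherits(fit, "ard_fit")) {
    Q <- build_ard_q(fit$rates)
    if (is.null(tree)) tree <- fit$tree
    if (is.null(tips)) tips <- fit$tips
    if (is.null(prior)) prior <- fit$prior
  } else {
    Q <- fit
    stopifnot(!is.null(tree), !is.null(tips))
  }
  m <- ctmc_marginals(tree, tips, Q, prior)
  out <- dplyr::left_join(
    tibble::tibble(
      node = seq_len(nrow(m)),
      is_tip = seq_len(nrow(m)) <= ape::Ntip(tree),
      p_absent = m[, 1], p_pericentromeric = m[, 2], p_distal = m[, 3]
    ),
    node_clades(tree), by = "node"
  )
  out <- out[, c("node", "clade", "is_tip",
                 "p_absent", "p_pericentromeric", "p_distal")]
  class(out) <- c("ancestral_table", class(out))
  out
}

ancestral_states <- function() c("absent", "pericentromeric", "distal")

#' Threshold-based state calls
#'
#' Adds a `call` column: a node is called for state `s` iff `P(s) >=
#' threshold` (inclusive), otherwise `"unknown"`. The default 75% threshold
#' is the probability cut-off used throughout the ancestral analysis.
#'
#' @param table An `ancestral_table` from [marginal_probs()].
#' @param threshold Probability threshold, in `(0.5, 1]`.
#' @return The table with an added `call` column; the fraction of known /
#'   unknown nodes is attached as attribute `call_summary`.
#' @export
classify_states <- function(table, threshold = 0.75) {
  stopifnot(is.data.frame(table))
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  }
  probs <- as.matrix(table[, c("p_absent", "p_pericentromeric", "p_distal")])
  best <- max.col(probs, ties.method = "first")
  pmax_ <- probs[cbind(seq_len(nrow(probs)), best)]
  call <- ifelse(pmax_ >= threshold, ancestral_states()[best], "unknown")
  out <- dplyr::mutate(table, call = call)
  attr(out, "call_summary") <- c(
    known = mean(call != "unknown"), unknown = mean(call == "unknown")
  )
  class(out) <- unique(c("ancestral_table", class(out)))
  out
}

#' Export a tree annotated with ancestral calls as Newick
#'
#' Writes the segment's tree with internal-node labels of the form
#' `call_percent`, where `percent` is the posterior probability of the
#' called state (or of the most probable state for `unknown` nodes).
#'
#' @param tree A `phylo` object.
#' @param called An `ancestral_table` with a `call` column.
#' @param file Optional path; when given the string is also written there.
#' @return The annotated Newick string, invisibly when `file` is given.
#' @export
export_annotated_newick <- function(tree, called, file = NULL) {
  stopifnot("call" %in% names(called))
  tab <- called[order(called$node), ]
  probs <- as.matrix(tab[, c("p_absent", "p_pericentromeric", "p_distal")])
  pct <- round(100 * apply(probs, 1, max))
  n_tip <- ape::Ntip(tree)
  lab <- paste0(tab$call, "_", pct)
  tree$node.label <- gsub("[,():;]", "_", lab[(n_tip + 1):nrow(tab)])
  out <- write_newick(tree)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Insertion/deletion event calls along branches
#'
#' Scans ancestor-descendant pairs with determinate presence calls (cluster
#' present = pericentromeric or distal; absent = absent). An insertion is a
#' transition absent -> present, a deletion the reverse. By default a node
#' whose parent is `"unknown"` is compared against its nearest determinate
#' ancestor, so each event is noted on the deepest node at which the new
#' state holds; `adjacent_only = TRUE` restricts to strictly adjacent pairs.
#' Events into tips are `"terminal"`, the rest `"deep"`.
#'
#' @param tree A `phylo` object.
#' @param called An `ancestral_table` with a `call` column
#'   (see [classify_states()]).
#' @param adjacent_only If `TRUE`, only parent-child pairs where both ends
#'   are determinate yield events.
#' @return A tibble with one row per event: `type` (insertion/deletion),
#'   `from_node`, `node` (reporting node), `clade`, `depth_class`
#'   (deep/terminal) and `support_pct` (posterior probability of the new
#'   presence status at the reporting node, as a percentage).
#' @export
call_events <- function(tree, called, adjacent_only = FALSE) {
  stopifnot("call" %in% names(called))
  n_tip <- ape::Ntip(tree)
  calls <- called$call[order(called$node)]
  presence <- ifelse(calls == "unknown", NA,
                     calls %in% c("pericentromeric", "distal"))
  probs <- as.matrix(called[order(called$node),
                            c("p_absent", "p_pericentromeric", "p_distal")])
  parent <- node_parent(tree)
  clades <- node_clades(tree)
  rows <- list()
  for (v in seq_along(presence)) {
    p <- parent[v]
    if (is.na(p) || is.na(presence[v])) next
    if (adjacent_only) {
      if (is.na(presence[p])) next
      anc <- p
    } else {
      anc <- p
      while (!is.na(anc) && is.na(presence[anc])) anc <- parent[anc]
      if (is.na(anc)) next
    }
    if (presence[anc] == presence[v]) next
    new_present <- presence[v]
    support <- if (new_present) {
      100 * (probs[v, 2] + probs[v, 3])
    } else {
      100 * probs[v, 1]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = if (new_present) "insertion" else "deletion",
      from_node = anc, node = v,
      clade = clades$clade[v],
      depth_class = if (v <= n_tip) "terminal" else "deep",
      support_pct = support
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(type = character(), from_node = integer(),
                          node = integer(), clade = character(),
                          depth_class = character(),
                          support_pct = numeric()))
  }
  dplyr::bind_rows(rows)
}
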