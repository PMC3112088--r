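#' Simulate a rooted tree
#'
#' Pure-birth (Yule) trees via [ape::rphylo()], bit-reproducible per seed.
#' A Yule tree with `n` tips has exactly `n - 1` internal branching events.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate.
#' @param seed Integer seed.
#' @return A rooted `phylo` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  withr::with_seed(derive_seed(seed, "simulate_tree"), {
    tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  })
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

#' Simulate a discrete character along a tree
#'
#' Exact continuous-time Markov simulation: the root state is drawn from
#' `prior` (or fixed by `root_state`), then each branch evolves by
#' exponential waiting times between jumps. The full node-state vector and
#' the per-branch jump counts are attached as attributes so lineage histories
#' can be audited.
#'
#' @param tree A `phylo` object.
#' @param Q Rate matrix (k x k).
#' @param root_state Optional fixed root state in `0:(k-1)`.
#' @param prior Root prior used when `root_state` is `NULL` (default
#'   uniform).
#' @param seed Integer seed.
#' @return Named integer vector of tip states in `0:(k-1)`, with attributes
#'   `node_states` (all nodes) and `n_jumps` (per postorder edge).
#' @export
simulate_character <- function(tree, Q, root_state = NULL, prior = NULL,
                               seed = 1L) {
  check_rate_matrix(Q)
  k <- nrow(Q)
  if (is.null(prior)) prior <- root_prior(k)
  eo <- postorder_edges(tree)
  n <- eo$n_nodes
  withr::with_seed(derive_seed(seed, "simulate_character"), {
    states <- rep(NA_integer_, n)
    states[eo$root] <- if (is.null(root_state)) {
      sample.int(k, 1, prob = prior) - 1L
    } else {
      as.integer(root_state)
    }
    n_jumps <- integer(nrow(eo$edge))
    for (e in rev(seq_len(nrow(eo$edge)))) {  # preorder: parents first
      s <- states[eo$edge[e, 1]]
      t_left <- eo$lens[e]
      repeat {
        out_rate <- -Q[s + 1, s + 1]
        if (out_rate <= 0) break
        w <- rexp(1, out_rate)
        if (w >= t_left) break
        t_left <- t_left - w
        probs <- Q[s + 1, ]
        probs[s + 1] <- 0
        s <- sample.int(k, 1, prob = probs) - 1L
        n_jumps[e] <- n_jumps[e] + 1L
      }
      states[eo$edge[e, 2]] <- s
    }
  })
  tips <- states[seq_len(ape::Ntip(tree))]
  names(tips) <- tree$tip.label
  attr(tips, "node_states") <- states
  attr(tips, "n_jumps") <- n_jumps
  tips
}

#' Simulate a binary trait pair
#'
#' Simulates the combined 4-state chain under the independent or dependent
#' generator and splits it into the two binary traits.
#'
#' @param tree A `phylo` object.
#' @param kind `"independent"` (4 rates) or `"dependent"` (8 rates).
#' @param rates Rate vector matching `kind`.
#' @param root_state Optional fixed combined root state in `0:3`.
#' @param seed Integer seed.
#' @return A tibble (`taxon`, `centromere`, `cluster`) with the simulated
#'   combined states attached as attribute `combined`.
#' @export
simulate_pair <- function(tree, kind = c("independent", "dependent"),
                          rates, root_state = NULL, seed = 1L) {
  kind <- match.arg(kind)
  n_expected <- if (kind == "independent") 4L else 8L
  if (length(rates) != n_expected) {
    stop(kind, " model needs ", n_expected, " rates", call. = FALSE)
  }
  Q <- if (kind == "independent") {
    build_independent_q(rates[1], rates[2], rates[3], rates[4])
  } else {
    build_dependent_q(rates)
  }
  combined <- simulate_character(tree, Q, root_state = root_state,
                                 seed = derive_seed(seed, "simulate_pair"))
  out <- tibble::tibble(
    taxon = names(combined),
    centromere = as.integer(combined >= 2L),
    cluster = as.integer(combined %% 2L)
  )
  attr(out, "combined") <- combined
  out
}
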