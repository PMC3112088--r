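# Independent oracles used across the suite: exhaustive enumeration over all
# internal-node state assignments, and small random problem generators.
# These never call the pruning code they are meant to check.

# Enumerate every assignment of states to internal nodes; tips are summed
# over their observation vectors. Returns the total likelihood and the
# per-node marginal posterior (tips included).
brute_force_posterior <- function(tree, tips, Q, prior = NULL) {
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  tips <- tips[tree$tip.label, , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  internals <- (n_tip + 1L):n_all
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  total <- 0
  marg <- matrix(0, n_all, k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    # probability of this internal assignment, tips integrated out
    p <- prior[assign_int[1]]  # internals[1] is the root
    tipw <- rep(NA_real_, n_tip)
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      sa <- assign_int[match(a, internals)]
      if (b > n_tip) {
        sb <- assign_int[match(b, internals)]
        p <- p * P[[e]][sa, sb]
      } else {
        w <- sum(P[[e]][sa, ] * tips[b, ])
        tipw[b] <- w
        p <- p * w
      }
      if (p == 0) break
    }
    if (p == 0) next
    total <- total + p
    for (i in seq_along(internals)) {
      marg[internals[i], assign_int[i]] <- marg[internals[i], assign_int[i]] + p
    }
    # tip marginals: re-split the tip weight over its compatible states
    for (b in seq_len(n_tip)) {
      e <- which(tree$edge[, 2] == b)
      sa <- assign_int[match(tree$edge[e, 1], internals)]
      contrib <- P[[e]][sa, ] * tips[b, ]
      marg[b, ] <- marg[b, ] + p * contrib / sum(contrib)
    }
  }
  list(loglik = log(total), marginals = marg / total)
}

# Random rooted tree with branch lengths, via a seeded coalescent shape.
random_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips, rooted = TRUE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  })
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

# Random k-state generator with off-diagonal rates in [lo, hi].
random_q <- function(k, seed, lo = 0.1, hi = 2) {
  withr::with_seed(seed, {
    Q <- matrix(stats::runif(k * k, lo, hi), k, k)
  })
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Random tip observation matrix: mostly observed states, some missing.
random_tips <- function(tree, k, seed, p_missing = 0.15) {
  withr::with_seed(seed, {
    st <- sample.int(k, ape::Ntip(tree), replace = TRUE) - 1L
    miss <- stats::runif(ape::Ntip(tree)) < p_missing
  })
  st_chr <- as.character(st)
  st_chr[miss] <- "?"
  rdnaevol::tip_data(stats::setNames(st_chr, tree$tip.label), k = k)
}
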