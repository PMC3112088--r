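test_that("marginal posteriors equal brute-force enumeration on small trees", {
  for (seed in 1:12) {
    k <- 3
    tr <- random_tree(3 + (seed %% 4), seed)
    Q <- random_q(k, seed + 50)
    tips <- random_tips(tr, k, seed + 90)
    bf <- brute_force_posterior(tr, tips, Q)
    m <- rdnaevol:::ctmc_marginals(tr, tips, Q)
    expect_equal(m, bf$marginals, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("invariant columns reconstruct the observed state everywhere", {
  tr <- random_tree(8, 3)
  tips <- tip_data(setNames(rep("0", 8), tr$tip.label), k = 3)
  fit <- fit_ard(tr, tips, n_restarts = 1, seed = 1)
  tab <- marginal_probs(fit)
  # every non-root node is reconstructed in the observed state; the root can
  # sit on the uniform-prior ridge where unobserved states decay instantly
  root <- ape::Ntip(tr) + 1L
  expect_true(all(tab$p_absent[tab$node != root] > 0.999))
  # no flow out of the observed state: those two rates hit the lower bound
  expect_lt(max(fit$rates[c("q01", "q02")]), 1e-5)
  # fitted likelihood at least that of the no-change model (probability 1/3)
  expect_gte(fit$loglik, log(1 / 3) - 1e-6)
})

test_that("symmetric cherry with symmetric rates gives a 50/50 root", {
  tr <- parse_newick("(A:1,B:1);")
  tips <- tip_data(c(A = "0", B = "1"), k = 3)
  Q <- build_ard_q(c(1, 0, 1, 0, 0, 0))  # symmetric 0<->1, state 2 unreachable
  m <- rdnaevol:::ctmc_marginals(tr, tips, Q)
  expect_equal(m[3, 1], m[3, 2], tolerance = 1e-10)
})

test_that("fit_ard is reproducible and reaches at least the true-rate lnL", {
  tr <- simulate_tree(40, seed = 9)
  Q <- build_ard_q(c(0.8, 0.3, 0.6, 0.4, 1.2, 0.2))
  x <- simulate_character(tr, Q, root_state = 0, seed = 2)
  tips <- tip_data(x, k = 3)
  f1 <- fit_ard(tr, tips, n_restarts = 2, seed = 5)
  f2 <- fit_ard(tr, tips, n_restarts = 2, seed = 5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_gte(f1$loglik, log_likelihood(tr, tips, Q) - 1e-6)
  expect_error(fit_ard(tr, tip_data(setNames(rep("?", 40), tr$tip.label))),
               "missing")
})

test_that("classify_states applies the inclusive threshold", {
  tab <- tibble::tibble(
    node = 1:4, clade = letters[1:4], is_tip = FALSE,
    p_absent = c(0.80, 0.50, 0.75, 0.20),
    p_pericentromeric = c(0.15, 0.50, 0.20, 0.15),
    p_distal = c(0.05, 0.00, 0.05, 0.65)
  )
  out <- classify_states(tab, threshold = 0.75)
  expect_equal(out$call, c("absent", "unknown", "absent", "unknown"))
  expect_error(classify_states(tab, threshold = 0.5), "threshold")
  expect_error(classify_states(tab, threshold = 1.01), "threshold")
})

test_that("raising the threshold never decreases the unknown count", {
  tr <- random_tree(12, 4)
  Q <- random_q(3, 11)
  tips <- random_tips(tr, 3, 13, p_missing = 0)
  tab <- marginal_probs(Q, tree = tr, tips = tips)
  n_unknown <- vapply(
    c(0.6, 0.75, 0.9, 0.99),
    function(th) sum(classify_states(tab, th)$call == "unknown"),
    numeric(1)
  )
  expect_true(all(diff(n_unknown) >= 0))
})

test_that("call_events matches a per-branch scan when all calls are known", {
  for (seed in 1:8) {
    tr <- random_tree(10, seed)
    n_all <- ape::Ntip(tr) + tr$Nnode
    withr::with_seed(seed + 500, {
      calls <- sample(c("absent", "pericentromeric", "distal"), n_all,
                      replace = TRUE)
    })
    tab <- tibble::tibble(
      node = seq_len(n_all), clade = "", is_tip = FALSE,
      p_absent = as.numeric(calls == "absent"),
      p_pericentromeric = as.numeric(calls == "pericentromeric"),
      p_distal = as.numeric(calls == "distal"),
      call = calls
    )
    ev <- call_events(tr, tab)
    # oracle: scan every branch independently
    present <- calls %in% c("pericentromeric", "distal")
    expected <- sum(present[tr$edge[, 1]] != present[tr$edge[, 2]])
    expect_equal(nrow(ev), expected)
    expect_lte(nrow(ev), nrow(tr$edge))
    if (nrow(ev)) {
      gains <- present[ev$node] & !present[ev$from_node]
      expect_equal(ev$type == "insertion", gains)
    }
  }
})

test_that("unknown parents attribute events to the deepest determinate node", {
  # root present -> unknown -> tip absent: one deletion vs none adjacent-only
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  tab <- tibble::tibble(
    node = 1:5, clade = "", is_tip = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    p_absent = c(1, 1, 0, 0.05, 0.4),
    p_pericentromeric = c(0, 0, 1, 0.95, 0.6),
    p_distal = 0
  )
  tab <- classify_states(tab, 0.75)
  expect_equal(tab$call[5], "unknown")  # the A+B ancestor
  ev <- call_events(tr, tab)
  expect_equal(sort(ev$type), c("deletion", "deletion"))
  expect_equal(sort(ev$from_node), c(4L, 4L))  # attributed past the unknown
  ev_adj <- call_events(tr, tab, adjacent_only = TRUE)
  expect_equal(nrow(ev_adj), 0)
})

test_that("the recurrent gain-loss pattern on one segment is recovered", {
  # present at the genus root; lost on the pygmy-mouse stem and on the
  # western-clade stem; regained on one island sister pair below it
  fx <- mus_study_fixture()
  tr <- fx$tree
  cl <- node_clades(tr)
  n_tip <- ape::Ntip(tr)
  nann <- c("M_mattheyi", "M_haussa", "M_indutus", "M_musculoides",
            "M_minutoides")
  eur <- c("M_spretus", "M_spicilegus", "M_cypriacus", "M_macedonicus",
           "M_m_castaneus", "M_m_musculus", "M_m_domesticus")
  cypmac <- c("M_cypriacus", "M_macedonicus")
  in_clade <- function(node, taxa) {
    tips <- strsplit(cl$clade[cl$node == node], ",")[[1]]
    all(tips %in% taxa)
  }
  n_all <- n_tip + tr$Nnode
  call <- rep("pericentromeric", n_all)
  for (v in seq_len(n_all)) {
    if (in_clade(v, nann) || (in_clade(v, eur) && !in_clade(v, cypmac))) {
      call[v] <- "absent"
    }
  }
  tab <- tibble::tibble(
    node = seq_len(n_all), clade = cl$clade, is_tip = seq_len(n_all) <= n_tip,
    p_absent = as.numeric(call == "absent"),
    p_pericentromeric = as.numeric(call == "pericentromeric"),
    p_distal = 0, call = call
  )
  ev <- call_events(tr, tab)
  expect_equal(sum(ev$type == "deletion"), 2)
  expect_equal(sum(ev$type == "insertion"), 1)
  ins <- ev[ev$type == "insertion", ]
  expect_equal(ins$clade, "M_cypriacus,M_macedonicus")
  expect_true(all(ev$depth_class == "deep"))
})

test_that("annotated newick export carries node calls and re-parses", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  tab <- tibble::tibble(
    node = 1:5, clade = "", is_tip = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    p_absent = c(1, 1, 0, 0.05, 0.9),
    p_pericentromeric = c(0, 0, 1, 0.95, 0.1),
    p_distal = 0
  )
  tab <- classify_states(tab, 0.75)
  nwk <- export_annotated_newick(tr, tab)
  expect_match(nwk, "pericentromeric_95")
  expect_match(nwk, "absent_90")
  reparsed <- parse_newick(nwk)
  expect_true(ape::all.equal.phylo(reparsed, tr, use.edge.length = TRUE))
  f <- withr::local_tempfile(fileext = ".nwk")
  export_annotated_newick(tr, tab, file = f)
  expect_true(file.exists(f))
})

test_that("tidy and glance summarise an ARD fit", {
  tr <- random_tree(6, 2)
  tips <- random_tips(tr, 3, 3, p_missing = 0)
  fit <- fit_ard(tr, tips, n_restarts = 1, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_equal(td$term, c("q01", "q02", "q10", "q12", "q20", "q21"))
  gl <- glance(fit)
  expect_equal(gl$n_rates, 6L)
  expect_equal(gl$logLik, fit$loglik)
})
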