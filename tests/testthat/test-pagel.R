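test_that("independent generator has 4 free rates, dependent 8, df = 4", {
  qi <- build_independent_q(1, 2, 3, 4)
  expect_equal(unname(rowSums(qi)), rep(0, 4), tolerance = 1e-12)
  off_i <- qi[row(qi) != col(qi)]
  expect_equal(length(unique(off_i[off_i > 0])), 4)
  # simultaneous double flips are forbidden
  expect_equal(unname(qi["00", "11"]), 0)
  expect_equal(unname(qi["11", "00"]), 0)
  expect_equal(unname(qi["01", "10"]), 0)
  expect_equal(unname(qi["10", "01"]), 0)

  qd <- build_dependent_q(1:8)
  off_d <- qd[row(qd) != col(qd)]
  expect_equal(sum(off_d > 0), 8)
  expect_equal(length(unique(off_d[off_d > 0])), 8)
  expect_equal(unname(qd["00", "11"]), 0)
  expect_equal(8L - 4L, lrt(-1, -1)$df)
})

test_that("dependent model with independence equalities equals independent", {
  a1 <- 0.7; b1 <- 0.2; a2 <- 1.3; b2 <- 0.5
  qd <- build_dependent_q(c(a2, a1, b2, a1, b1, a2, b1, b2))
  expect_equal(qd, build_independent_q(a1, b1, a2, b2), tolerance = 1e-14)
})

test_that("trait-2-frozen independent model reduces to the 2-state chain", {
  a1 <- 0.9; b1 <- 0.4
  qi <- build_independent_q(a1, b1, 0, 0)
  tr <- random_tree(6, 8)
  withr::with_seed(3, t1 <- sample(0:1, 6, replace = TRUE))
  pair <- tibble::tibble(taxon = tr$tip.label, centromere = t1, cluster = 0)
  ll4 <- log_likelihood(tr, pair_tip_data(pair), qi, rep(0.25, 4))
  q2 <- matrix(c(-a1, a1, b1, -b1), 2, 2, byrow = TRUE)
  tips2 <- tip_data(setNames(as.character(t1), tr$tip.label), k = 2)
  ll2 <- log_likelihood(tr, tips2, q2, c(0.5, 0.5))
  # the frozen trait contributes its own factor 1/2 through the root prior
  expect_equal(ll4, ll2 + log(0.5), tolerance = 1e-10)
})

test_that("independent-pair lnL factorizes into single-trait lnLs", {
  for (seed in 1:25) {
    tr <- random_tree(4 + seed %% 6, seed)
    withr::with_seed(seed + 1000, {
      r <- runif(4, 0.1, 2)
      t1 <- sample(0:1, ape::Ntip(tr), replace = TRUE)
      t2 <- sample(0:1, ape::Ntip(tr), replace = TRUE)
    })
    pair <- tibble::tibble(taxon = tr$tip.label, centromere = t1,
                           cluster = t2)
    qi <- build_independent_q(r[1], r[2], r[3], r[4])
    ll_joint <- log_likelihood(tr, pair_tip_data(pair), qi, rep(0.25, 4))
    q1 <- matrix(c(-r[1], r[1], r[2], -r[2]), 2, 2, byrow = TRUE)
    q2 <- matrix(c(-r[3], r[3], r[4], -r[4]), 2, 2, byrow = TRUE)
    ll1 <- log_likelihood(tr, tip_data(setNames(as.character(t1),
                                                tr$tip.label), k = 2),
                          q1, c(0.5, 0.5))
    ll2 <- log_likelihood(tr, tip_data(setNames(as.character(t2),
                                                tr$tip.label), k = 2),
                          q2, c(0.5, 0.5))
    expect_equal(ll_joint, ll1 + ll2, tolerance = 1e-6)
  }
})

test_that("pair_tip_data handles missing values on either trait", {
  pair <- tibble::tibble(taxon = c("a", "b", "c"),
                         centromere = c(1, NA, 0),
                         cluster = c("0", "1", "?"))
  m <- pair_tip_data(pair)
  expect_equal(unname(m["a", ]), c(0, 0, 1, 0))  # (1,0) -> state "10"
  expect_equal(unname(m["b", ]), c(0, 1, 0, 1))  # trait1 free, trait2 = 1
  expect_equal(unname(m["c", ]), c(1, 1, 0, 0))  # trait1 = 0, trait2 free
  expect_error(pair_tip_data(tibble::tibble(taxon = "a", centromere = 2,
                                            cluster = 0)), "0, 1")
})

test_that("lrt reproduces the published statistics from printed lnLs", {
  expect_equal(lrt(-21.7, -16.3)$statistic, 10.8, tolerance = 1e-9)
  expect_equal(lrt(-21.3, -17.5)$statistic, 7.6, tolerance = 1e-9)
  r0 <- lrt(-5, -5)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(lrt(-5, -6), "optimizer failure")
  # df = 4 chi-square upper tail has closed form exp(-x/2) (1 + x/2)
  for (x in c(0.3, 2, 7.6, 10.8, 25)) {
    expect_equal(pchisq(x, 4, lower.tail = FALSE),
                 exp(-x / 2) * (1 + x / 2), tolerance = 1e-10)
  }
})

test_that("nesting holds: dependent fit never falls below independent", {
  for (seed in 1:5) {
    tr <- simulate_tree(30, seed = seed)
    pt <- simulate_pair(tr, "independent", c(0.8, 0.6, 1.1, 0.4),
                        seed = seed + 10)
    ind <- fit_pair_model(tr, pt, "independent", n_restarts = 1, seed = 1)
    dep <- fit_pair_model(tr, pt, "dependent", n_restarts = 1, seed = 1,
                          independent_fit = ind)
    expect_gte(dep$loglik, ind$loglik - 1e-6)
  }
})

test_that("invariant trait pairs give near-zero rates and statistic", {
  tr <- simulate_tree(20, seed = 2)
  pair <- tibble::tibble(taxon = tr$tip.label, centromere = 1, cluster = 0)
  ind <- fit_pair_model(tr, pair, "independent", n_restarts = 1, seed = 1)
  dep <- fit_pair_model(tr, pair, "dependent", n_restarts = 1, seed = 1,
                        independent_fit = ind)
  r <- lrt(ind, dep)
  expect_lt(r$statistic, 1e-3)
  expect_gt(r$p_value, 0.999)
})

test_that("a strongly dependent pair is detected", {
  tr <- simulate_tree(100, seed = 5)
  # trait 2 can only be gained while trait 1 is present
  pt <- simulate_pair(tr, "dependent", c(0, 0.5, 3, 0.5, 0.5, 2, 0.5, 0.1),
                      root_state = 0, seed = 11)
  ind <- fit_pair_model(tr, pt, "independent", n_restarts = 1, seed = 1)
  dep <- fit_pair_model(tr, pt, "dependent", n_restarts = 1, seed = 1,
                        independent_fit = ind)
  expect_lt(lrt(ind, dep)$p_value, 0.05)
})

test_that("run_all_segments retains, fits and sorts segments", {
  tr <- simulate_tree(12, seed = 3)
  taxa <- tr$tip.label
  mat <- tibble::tibble(
    taxon = taxa,
    s1 = rep(c("0", "1"), 6),       # variable, retained
    s2 = rep("0", 12),              # cluster-free, dropped
    s3 = rep(c("0", "2"), 6),       # telomeric only, dropped
    s4 = c(rep("1", 6), rep("0", 6))
  )
  cen <- tidyr::expand_grid(taxon = taxa, segment = c("s1", "s2", "s3", "s4"))
  withr::with_seed(4, cen$centromere <- sample(0:1, nrow(cen), replace = TRUE))
  expect_equal(retain_segments(mat), c("s1", "s4"))
  screen <- run_all_segments(tr, mat, cen, n_restarts = 1, seed = 1)
  expect_equal(nrow(screen), 2)
  expect_true(all(screen$df == 4))
  expect_true(!is.unsorted(screen$p_value))
  gl <- glance(screen)
  expect_equal(gl$n_segments, 2)
})
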