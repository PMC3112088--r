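#' Generator for two independently evolving binary traits
#'
#' Combined states are ordered `(0,0), (0,1), (1,0), (1,1)` where the pair is
#' `(trait1, trait2)` — here (centromere, cluster). Under independence each
#' trait's gain/loss rate is the same whatever the other trait's state, and
#' simultaneous changes of both traits have rate zero, leaving 4 free
#' parameters.
#'
#' @param alpha1,beta1 Gain and loss rate of trait 1.
#' @param alpha2,beta2 Gain and loss rate of trait 2.
#' @return A 4x4 rate matrix.
#' @export
build_independent_q <- function(alpha1, beta1, alpha2, beta2) {
  r <- c(alpha1, beta1, alpha2, beta2)
  if (length(r) != 4 || any(r < 0)) {
    stop("need four non-negative rates", call. = FALSE)
  }
  # dependent parameterisation with the four independence equalities imposed
  build_dependent_q(c(alpha2, alpha1, beta2, alpha1, beta1, alpha2,
                      beta1, beta2))
}

#' Generator for two co-evolving binary traits
#'
#' Each single-trait transition rate is conditioned on the other trait's
#' current state, giving 8 free parameters; simultaneous changes of both
#' traits keep rate zero. Rates are given in the order
#' `q12, q13, q21, q24, q31, q34, q42, q43` over the combined states
#' `1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1)`:
#' gain2|t1=0, gain1|t2=0, loss2|t1=0, gain1|t2=1,
#' loss1|t2=0, gain2|t1=1, loss1|t2=1, loss2|t1=1.
#'
#' @param rates Numeric vector of eight non-negative rates.
#' @return A 4x4 rate matrix with dimnames `c("00","01","10","11")`.
#' @export
build_dependent_q <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) == 8)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  s <- c("00", "01", "10", "11")
  q <- matrix(0, 4, 4, dimnames = list(s, s))
  q[1, 2] <- rates[1]  # q12: 00 -> 01 (gain trait2 | trait1 absent)
  q[1, 3] <- rates[2]  # q13: 00 -> 10 (gain trait1 | trait2 absent)
  q[2, 1] <- rates[3]  # q21: 01 -> 00 (loss trait2 | trait1 absent)
  q[2, 4] <- rates[4]  # q24: 01 -> 11 (gain trait1 | trait2 present)
  q[3, 1] <- rates[5]  # q31: 10 -> 00 (loss trait1 | trait2 absent)
  q[3, 4] <- rates[6]  # q34: 10 -> 11 (gain trait2 | trait1 present)
  q[4, 2] <- rates[7]  # q42: 11 -> 01 (loss trait1 | trait2 present)
  q[4, 3] <- rates[8]  # q43: 11 -> 10 (loss trait2 | trait1 present)
  diag(q) <- -rowSums(q)
  q
}

dependent_rate_names <- function() {
  c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
}

#' Combined observation vectors for a binary trait pair
#'
#' Builds taxa-by-4 observation vectors over the combined states
#' `(0,0),(0,1),(1,0),(1,1)`. A `"?"`/`NA` on either trait sets all compatible
#' combined states to one.
#'
#' @param pair A data frame with columns `taxon`, `centromere`, `cluster`
#'   (values 0, 1 or NA/`"?"`).
#' @return A numeric matrix (taxa x 4) with taxon rownames.
#' @export
pair_tip_data <- function(pair) {
  stopifnot(all(c("taxon", "centromere", "cluster") %in% names(pair)))
  to01 <- function(x) {
    x <- as.character(x)
    x[x == "?"] <- NA
    v <- suppressWarnings(as.integer(x))
    if (any(!is.na(v) & !(v %in% 0:1))) {
      stop("trait values must be 0, 1 or missing", call. = FALSE)
    }
    v
  }
  t1 <- to01(pair$centromere)
  t2 <- to01(pair$cluster)
  m <- matrix(0, nrow(pair), 4,
              dimnames = list(pair$taxon, c("00", "01", "10", "11")))
  comb1 <- c(0L, 0L, 1L, 1L)  # trait1 value of combined state
  comb2 <- c(0L, 1L, 0L, 1L)  # trait2 value
  for (i in seq_len(nrow(pair))) {
    ok1 <- if (is.na(t1[i])) rep(TRUE, 4) else comb1 == t1[i]
    ok2 <- if (is.na(t2[i])) rep(TRUE, 4) else comb2 == t2[i]
    m[i, ok1 & ok2] <- 1
  }
  m
}

#' Fit the independent or dependent pair model by maximum likelihood
#'
#' Bounded multi-start ML as in [fit_ard()]. The dependent fit is
#' warm-started from the independent MLE (mapped into the 8-rate space), which
#' guarantees `lnL_dep >= lnL_indep` up to optimizer tolerance, plus jittered
#' restarts under a fixed seed.
#'
#' @param tree A `phylo` object.
#' @param pair A data frame (`taxon`, `centromere`, `cluster`) or a matrix
#'   from [pair_tip_data()].
#' @param kind `"independent"` or `"dependent"`.
#' @param prior Root prior over the four combined states (default uniform).
#' @param n_restarts Random restarts added to the default/warm starts.
#' @param seed Seed for restart draws.
#' @param bounds Rate bounds on the unit-height tree scale.
#' @param independent_fit Optional `pagel_fit` of kind `"independent"` on the
#'   same data, reused for the dependent warm start instead of refitting.
#' @return A `pagel_fit` object: `kind`, named MLE `rates`, `loglik`,
#'   `convergence`, `n_starts`.
#' @export
fit_pair_model <- function(tree, pair, kind = c("independent", "dependent"),
                           prior = NULL, n_restarts = 4L, seed = 1L,
                           bounds = c(1e-8, 100), independent_fit = NULL) {
  kind <- match.arg(kind)
  tips <- if (is.matrix(pair)) pair else pair_tip_data(pair)
  tips <- align_tips(tree, tips)
  if (all(tips == 1)) stop("all tips are missing", call. = FALSE)
  if (kind == "independent") {
    fit <- fit_ctmc_rates(
      tree, tips, q_builder = function(r) build_independent_q(r[1], r[2],
                                                              r[3], r[4]),
      n_rates = 4L, prior = prior, n_restarts = n_restarts, seed = seed,
      bounds = bounds
    )
    rates <- setNames(fit$rates, c("alpha1", "beta1", "alpha2", "beta2"))
  } else {
    # warm start at the independent MLE, mapped into the 8-rate space
    ind <- independent_fit
    if (is.null(ind) || ind$kind != "independent") {
      ind <- fit_pair_model(tree, tips, "independent", prior = prior,
                            n_restarts = n_restarts, seed = seed,
                            bounds = bounds)
    }
    r <- attr(ind, "par_scaled")
    warm <- log(pmax(c(r[3], r[1], r[4], r[1], r[2], r[3], r[2], r[4]),
                     bounds[1]))
    jitters <- withr::with_seed(
      derive_seed(seed, "fit_pair_dependent"),
      replicate(n_restarts, warm + stats::rnorm(8, 0, 0.5), simplify = FALSE)
    )
    fit <- fit_ctmc_rates(
      tree, tips, q_builder = build_dependent_q, n_rates = 8L, prior = prior,
      n_restarts = 0L, seed = seed, bounds = bounds,
      extra_starts = c(list(warm), jitters, list(rep(log(0.5), 8)))
    )
    rates <- setNames(fit$rates, dependent_rate_names())
  }
  structure(
    list(kind = kind, rates = rates, loglik = fit$loglik,
         convergence = fit$convergence, n_starts = fit$n_starts),
    class = "pagel_fit", par_scaled = fit$par_scaled
  )
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat("Pair-trait CTMC fit (", x$kind, " model, ",
      length(x$rates), " rates)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Likelihood-ratio test of correlated evolution
#'
#' Compares the dependent (8-rate) against the independent (4-rate) model:
#' statistic `2 * (lnL_dep - lnL_indep)`, referred to a chi-square
#' distribution with `df = 4` (upper tail). Because the models are nested the
#' statistic is clamped at zero when it falls within tolerance below zero; a
#' larger violation signals optimizer failure and raises an error.
#'
#' @param lnl_indep,lnl_dep Log-likelihoods (numbers or `pagel_fit` objects).
#' @param tol Nesting tolerance.
#' @return A `pagel_lrt` tibble with `lnl_indep`, `lnl_dep`, `statistic`,
#'   `df`, `p_value`.
#' @examples
#' lrt(-21.7, -16.3)  # statistic 10.8
#' @export
lrt <- function(lnl_indep, lnl_dep, tol = 1e-6) {
  if (inherits(lnl_indep, "pagel_fit")) lnl_indep <- lnl_indep$loglik
  if (inherits(lnl_dep, "pagel_fit")) lnl_dep <- lnl_dep$loglik
  stopifnot(is.finite(lnl_indep), is.finite(lnl_dep))
  stat <- 2 * (lnl_dep - lnl_indep)
  if (stat < -tol) {
    stop("dependent log-likelihood below independent beyond tolerance: ",
         "optimizer failure", call. = FALSE)
  }
  stat <- max(stat, 0)
  out <- tibble::tibble(
    lnl_indep = lnl_indep, lnl_dep = lnl_dep,
    statistic = stat, df = 4L,
    p_value = pchisq(stat, df = 4, lower.tail = FALSE)
  )
  class(out) <- c("pagel_lrt", class(out))
  out
}

#' Segments retained for the correlated-evolution screen
#'
#' A segment enters the screen only if a pericentromeric cluster (state 1)
#' was observed on it in at least one taxon; segments with no cluster
#' anywhere, or with clusters only at the telomeric (distal, state 2)
#' position, are excluded.
#'
#' @param matrix A character matrix tibble (`taxon` column + segment columns
#'   with values `"0","1","2","?"`).
#' @return Character vector of retained segment names, in matrix order.
#' @export
retain_segments <- function(matrix) {
  segs <- setdiff(names(matrix), "taxon")
  keep <- vapply(segs, function(s) any(matrix[[s]] == "1", na.rm = TRUE),
                 logical(1))
  segs[keep]
}

#' Correlated-evolution screen over all segments
#'
#' Runs the dependent-vs-independent likelihood-ratio test for every retained
#' segment, pairing per-taxon centromere presence with cluster presence
#' (states 1 and 2 collapsed to presence; `"?"` stays missing).
#'
#' @param tree A `phylo` object.
#' @param matrix Character matrix tibble (see [encode_matrix()]).
#' @param centromeres Long tibble with columns `taxon`, `segment`,
#'   `centromere` (0/1, `NA` allowed).
#' @param alpha Significance level for flagging.
#' @param n_restarts,seed Passed to [fit_pair_model()].
#' @return A `pagel_screen` tibble sorted by p-value: `segment`, `lnl_indep`,
#'   `lnl_dep`, `statistic`, `df`, `p_value`, `significant`. The number of
#'   significant segments is attached as attribute `n_significant`.
#' @export
run_all_segments <- function(tree, matrix, centromeres, alpha = 0.05,
                             n_restarts = 2L, seed = 1L) {
  segs <- retain_segments(matrix)
  res <- purrr::map_dfr(segs, function(s) {
    pair <- segment_pair(matrix, centromeres, s)
    ind <- fit_pair_model(tree, pair, "independent",
                          n_restarts = n_restarts, seed = seed)
    dep <- fit_pair_model(tree, pair, "dependent",
                          n_restarts = n_restarts, seed = seed,
                          independent_fit = ind)
    dplyr::mutate(lrt(ind, dep), segment = s, .before = 1)
  })
  res <- dplyr::arrange(res, .data$p_value, .data$segment)
  res$significant <- res$p_value < alpha
  attr(res, "alpha") <- alpha
  attr(res, "n_significant") <- sum(res$significant)
  class(res) <- c("pagel_screen", class(res))
  res
}

# Pair (centromere, cluster-presence) trait table for one segment.
segment_pair <- function(matrix, centromeres, segment) {
  st <- matrix[[segment]]
  cluster <- ifelse(st == "?", NA, as.integer(st %in% c("1", "2")))
  cen <- centromeres[centromeres$segment == segment, , drop = FALSE]
  cen_v <- cen$centromere[match(matrix$taxon, cen$taxon)]
  tibble::tibble(taxon = matrix$taxon, centromere = cen_v, cluster = cluster)
}
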