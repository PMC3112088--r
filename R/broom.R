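#' Tidy an ARD fit
#' @param x An `ard_fit` object.
#' @param ... Unused.
#' @return One row per transition rate: `term`, `from`, `to`, `estimate`.
#' @method tidy ard_fit
#' @export
tidy.ard_fit <- function(x, ...) {
  states <- ancestral_states()
  idx <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  tibble::tibble(
    term = names(x$rates),
    from = states[idx[, 1]], to = states[idx[, 2]],
    estimate = unname(x$rates)
  )
}

#' Glance at an ARD fit
#' @param x An `ard_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `nobs`, `n_rates`, `converged`,
#'   `n_starts`.
#' @method glance ard_fit
#' @export
glance.ard_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = nrow(x$tips), n_rates = 6L,
                 converged = x$convergence, n_starts = x$n_starts)
}

#' Tidy a pair-trait fit
#' @param x A `pagel_fit` object.
#' @param ... Unused.
#' @return One row per rate: `term`, `estimate`.
#' @method tidy pagel_fit
#' @export
tidy.pagel_fit <- function(x, ...) {
  tibble::tibble(term = names(x$rates), estimate = unname(x$rates))
}

#' Glance at a pair-trait fit
#' @param x A `pagel_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `kind`, `logLik`, `n_rates`, `converged`.
#' @method glance pagel_fit
#' @export
glance.pagel_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, logLik = x$loglik,
                 n_rates = length(x$rates), converged = x$convergence)
}

#' Tidy a correlated-evolution likelihood-ratio test
#' @param x A `pagel_lrt` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @method tidy pagel_lrt
#' @export
tidy.pagel_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value)
}

#' Glance at a segment screen
#' @param x A `pagel_screen` tibble.
#' @param ... Unused.
#' @return One-row tibble: `n_segments`, `n_significant`, `alpha`.
#' @method glance pagel_screen
#' @export
glance.pagel_screen <- function(x, ...) {
  tibble::tibble(n_segments = nrow(x),
                 n_significant = attr(x, "n_significant"),
                 alpha = attr(x, "alpha"))
}
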