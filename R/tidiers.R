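#' Tidy a reflectivity fit
#'
#' One row per parameter with the fitted value; bootstrap interval columns
#' are filled in after [refl_bootstrap()].
#'
#' @param x a [refl_fit()].
#' @param all include fixed parameters too (default: varying only).
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`, `conf.high`,
#'   `vary`.
#' @method tidy refl_fit
#' @export
tidy.refl_fit <- function(x, all = FALSE, ...) {
  p <- x$params
  out <- tibble(
    term = p$name, estimate = p$value,
    conf.low = NA_real_, conf.high = NA_real_, vary = p$vary
  )
  if (!is.null(x$bootstrap)) {
    iv <- x$bootstrap$intervals
    idx <- match(iv$term, out$term)
    out$conf.low[idx] <- iv$conf.low
    out$conf.high[idx] <- iv$conf.high
  }
  if (!all) out <- out[out$vary, ]
  out
}

#' Glance at a reflectivity fit
#'
#' @param x a [refl_fit()].
#' @param ... unused.
#' @return A one-row tibble: total and per-contrast-averaged chi-squared,
#'   problem size, optimizer bookkeeping.
#' @method glance refl_fit
#' @export
glance.refl_fit <- function(x, ...) {
  tibble(
    chisq_total = x$chisq_total,
    n_contrasts = nrow(x$chisq_per_contrast),
    n_points = sum(x$chisq_per_contrast$n),
    n_par = sum(x$params$vary),
    n_evals = x$n_evals,
    convergence = x$convergence,
    seed = x$seed
  )
}
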