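#' Plot a reflectivity curve
#'
#' Log-log reflectivity versus Q, with error bars when a `dr` column is
#' present.
#'
#' @param object a [refl_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot refl_curve
#' @export
autoplot.refl_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$r)) +
    ggplot2::geom_point(size = 0.8)
  if (!is.null(object$dr)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$r - .data$dr, .Machine$double.xmin),
        ymax = .data$r + .data$dr
      ),
      linewidth = 0.3
    )
  }
  p +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(Q ~ (ring(A)^-1)),
      y = "Reflectivity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an SLD depth profile
#'
#' @param object output of [sld_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sld_profile_df
#' @export
autoplot.sld_profile_df <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$sld * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(z ~ (ring(A))),
      y = expression(SLD ~ (10^-6 ~ ring(A)^-2))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a multi-contrast fit: data and fitted curves
#'
#' Points are the observed reflectivities, lines the fitted model, one facet
#' per contrast.
#'
#' @param object a [refl_fit()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot refl_fit
#' @export
autoplot.refl_fit <- function(object, ...) {
  problem <- object$problem
  pv <- .par_values(problem)
  df <- dplyr::bind_rows(lapply(problem$contrasts, function(ct) {
    tibble(
      contrast = ct$name, q = ct$data$q, r = ct$data$r,
      dr = ct$data[["dr"]] %||% NA_real_,
      model = .contrast_model(problem, pv, ct)
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$r), size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "#c03030") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(Q ~ (ring(A)^-1)), y = "Reflectivity",
      title = sprintf("chi^2 = %.3g", object$chisq_total)
    ) +
    ggplot2::theme_minimal()
}
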