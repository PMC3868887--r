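#' Plot a mutual-information sweep
#'
#' `autoplot()` on a sweep draws the information surface as a heatmap with
#' the Kenyon-cell threshold on the x axis and the connectivity rate on the
#' y axis, facetted over any additional concentration / inhibition grid.
#' When only one of the two axes was swept, it falls back to
#' [plot_mi_curve()].
#'
#' @param object a `flymi_sweep` (summary form).
#' @param ... unused.
#' @return A ggplot object.
#' @examples
#' cfg <- experiment_config(
#'   n_odors = 3, n_trials = 16, n_flies = 2,
#'   theta = c(2, 4), r = c(0.3, 0.6), seed = 2
#' )
#' autoplot(mi_sweep(cfg))
#' @method autoplot flymi_sweep
#' @export
autoplot.flymi_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (length(unique(df$theta)) < 2 || length(unique(df$r)) < 2) {
    return(plot_mi_curve(object))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$theta, y = .data$r, fill = .data$mi_mean
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI (bits)") +
    ggplot2::labs(
      x = expression("Kenyon-cell threshold" ~ Theta),
      y = "connectivity rate r"
    ) +
    ggplot2::theme_minimal()
  p + sweep_facets(df)
}

#' @rdname autoplot.flymi_sweep
#' @param result a `flymi_sweep`.
#' @export
plot_mi_curve <- function(result, ...) {
  df <- tibble::as_tibble(result)
  df$condition <- ifelse(is.na(df$alpha), "no inhibition", sprintf("alpha = %g", df$alpha))
  xvar <- if (length(unique(df$theta)) > 1) "theta" else "concentration"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[xvar]], y = .data$mi_mean,
    colour = factor(.data$concentration), linetype = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = if (xvar == "theta") expression("Kenyon-cell threshold" ~ Theta) else "odor concentration",
      y = "mutual information (bits)", colour = "concentration",
      linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

sweep_facets <- function(df) {
  many_conc <- length(unique(df$concentration)) > 1
  many_alpha <- length(unique(df$alpha)) > 1
  if (many_conc && many_alpha) {
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$concentration),
      cols = ggplot2::vars(.data$alpha), labeller = "label_both"
    )
  } else if (many_conc) {
    ggplot2::facet_wrap(ggplot2::vars(.data$concentration), labeller = "label_both")
  } else if (many_alpha) {
    ggplot2::facet_wrap(ggplot2::vars(.data$alpha), labeller = "label_both")
  } else {
    NULL
  }
}
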