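#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a fitted lifespan trajectory with its data
#'
#' Population-level fitted curve with an approximate 95% pointwise band,
#' over the (optionally harmonized) observations.
#'
#' @param fit a `smooth_fit` or `harmonized_series`.
#' @param n_grid grid resolution.
#' @return a ggplot.
#' @export
plot_trajectory <- function(fit, n_grid = 200) {
  pts <- NULL
  if (inherits(fit, "harmonized_series")) {
    pts <- tibble::tibble(age = fit$age, y = fit$variance_adjusted)
    fit <- fit$fit
  } else {
    pts <- tibble::tibble(age = fit$data$ta^(1 / fit$alpha), y = fit$data$y)
  }
  grid <- seq(fit$age_range[1], fit$age_range[2], length.out = n_grid)
  pr <- predict_curve(fit, grid, se = TRUE)
  band <- tibble::tibble(age = grid, fit = pr$fit,
                         lo = pr$fit - 1.96 * pr$se, hi = pr$fit + 1.96 * pr$se)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$y),
                        alpha = 0.25, size = 0.6) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), linewidth = 0.8) +
    ggplot2::labs(x = "age (years)", y = "value") +
    ggplot2::theme_minimal()
}

#' Scatter of an embedding in one gradient plane
#'
#' @param embedding an `embedding_set`.
#' @param axes length-2 integer, which axes to plot (default SA vs VS).
#' @param labels optional per-vertex network labels for colouring.
#' @return a ggplot.
#' @export
plot_embedding <- function(embedding, axes = c(1, 2), labels = NULL) {
  co <- embedding$coords
  nm <- embedding$axis_names %||% paste0("axis", seq_len(ncol(co)))
  df <- tibble::tibble(x = co[, axes[1]], y = co[, axes[2]])
  if (!is.null(labels)) df$network <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = nm[axes[1]], y = nm[axes[2]]) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$network),
                               alpha = 0.8, size = 0.8)
}

#' Heat map of theme-level enrichment scores across ages
#'
#' @param theme_table output of [theme_summary()].
#' @return a ggplot.
#' @export
plot_theme_summary <- function(theme_table) {
  ggplot2::ggplot(theme_table,
                  ggplot2::aes(x = factor(.data$age), y = .data$theme,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "median -log10(q)") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}
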