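#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_tile geom_point
#'   geom_abline geom_segment geom_errorbar geom_col labs theme_minimal
#'   coord_equal coord_fixed scale_fill_gradient annotation_raster theme
#'   element_blank facet_wrap scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot a pair matrix as a grey array
#'
#' The 6 x 6 array with the off-diagonal range mapped onto the full grey
#' scale, black diagonal, axes in cardinal order.
#'
#' @param object A [pair_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pair_matrix
#' @export
autoplot.pair_matrix <- function(object, ...) {
  nm <- rownames(object$grey)
  d <- tidyr::expand_grid(row = nm, col = nm)
  d$grey <- as.vector(t(object$grey)) # row-major fill
  d$row <- factor(d$row, levels = rev(nm))
  d$col <- factor(d$col, levels = nm)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$grey)) +
    geom_tile() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "grey") +
    theme_minimal()
}

#' Show a rendered stimulus
#'
#' @param object A `macchia_stimulus` from [render_stimulus()].
#' @param ... Unused.
#' @return A ggplot wrapping the raster.
#' @method autoplot macchia_stimulus
#' @export
autoplot.macchia_stimulus <- function(object, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  ggplot() +
    annotation_raster(img, xmin = 0, xmax = w, ymin = 0, ymax = h) +
    ggplot2::xlim(0, w) + ggplot2::ylim(0, h) +
    coord_fixed(expand = FALSE) +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank()) +
    labs(x = NULL, y = NULL)
}

#' Observer responses against the cross-observer medians
#'
#' The normalisation diagnostic: each observer's raw responses plotted against
#' the cell medians, with the fitted per-observer lines; after normalisation
#' all lines collapse onto the identity.
#'
#' @param data A table from [normalize_observers()].
#' @return A ggplot.
#' @export
plot_normalization <- function(data) {
  fits <- observer_fits(data)
  ggplot(data, aes(x = .data$cell_median, y = .data$contrast,
                   colour = .data$observer_id)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(data = fits,
                aes(slope = .data$slope, intercept = .data$intercept,
                    colour = .data$observer_id)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "cross-observer cell median", y = "response",
         colour = "observer") +
    theme_minimal()
}

#' Quartile bars per pair
#'
#' Median with Q1-Q3 error bars per cardinal pair, faceted by condition.
#'
#' @param summary A tibble from [summarize_pairs()].
#' @return A ggplot.
#' @export
plot_pair_summary <- function(summary) {
  summary$pair <- factor(summary$pair, levels = cardinal_pairs()$pair)
  ggplot(summary, aes(x = .data$pair, y = .data$median, fill = .data$class)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$q1, ymax = .data$q3), width = 0.3) +
    facet_wrap(~condition) +
    scale_y_continuous(limits = c(0, NA)) +
    labs(x = NULL, y = "distinctiveness (Michelson contrast)") +
    theme_minimal()
}

#' Hexagon panel for one fiducial colour
#'
#' The colour circle seen from a fiducial cardinal: spokes to the five other
#' cardinals with thickness proportional to the normalised weights.
#'
#' @param hex A tibble from [hexagon_summary()].
#' @return A ggplot.
#' @export
plot_hexagon <- function(hex) {
  cc <- cardinal_colours()
  pos <- tibble(name = cc$name,
                x = cos(cc$hue * pi / 3),
                y = sin(cc$hue * pi / 3))
  f <- pos[match(hex$fiducial[1], pos$name), ]
  seg <- dplyr::left_join(hex, pos, by = c("other" = "name"))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = f$x, y = f$y, xend = .data$x, yend = .data$y,
                     linewidth = .data$weight)) +
    geom_point(data = pos, aes(x = .data$x, y = .data$y),
               colour = grDevices::rgb(cc$r, cc$g, cc$b), size = 5) +
    coord_equal() +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank()) +
    labs(x = NULL, y = NULL, linewidth = "weight")
}

#' Model comparison dot plot
#'
#' Kendall tau and Pearson r of each model against the observed medians, per
#' condition.
#'
#' @param comparison A tibble from [compare_models()].
#' @return A ggplot.
#' @export
plot_model_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison,
                              c("kendall_tau", "pearson_r"),
                              names_to = "statistic", values_to = "value")
  ggplot(long, aes(x = .data$condition, y = .data$value,
                   colour = .data$model, group = .data$model)) +
    geom_point(size = 2, position = ggplot2::position_dodge(width = 0.4)) +
    facet_wrap(~statistic) +
    scale_y_continuous(limits = c(-1, 1)) +
    labs(x = NULL, y = "correlation with observed medians") +
    theme_minimal()
}
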