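# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline geom_point
#'   geom_raster facet_wrap labs scale_fill_viridis_c theme_minimal
#'   geom_text coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot per-fold decoding accuracies
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$folds
  ggplot(df, aes(x = factor(.data$fold), y = .data$accuracy)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = "fold", y = "accuracy",
         title = sprintf("%s decoding (%s): mean accuracy %.3f",
                         object$target, object$scheme,
                         object$mean_accuracy)) +
    theme_minimal()
}

#' Axial slice montage of a volume map
#'
#' @param object a [volume_map()].
#' @param slices z indices to show (default: up to 12, evenly spaced).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.volume_map <- function(object, slices = NULL, ...) {
  d <- dim(object$values)
  slices <- slices %||% unique(round(seq(1, d[3], length.out = min(12, d[3]))))
  df <- purrr::map_dfr(slices, function(z) {
    tibble(x = rep(seq_len(d[1]), d[2]),
           y = rep(seq_len(d[2]), each = d[1]),
           z = z, value = as.vector(object$values[, , z]))
  })
  ggplot(df[!is.na(df$value), ], aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~z) +
    scale_fill_viridis_c(name = object$kind) +
    coord_equal() +
    theme_minimal()
}

#' Plot a 2-D group affect space
#'
#' @param object an `indscal_solution` or `statis_solution`.
#' @param labels optional tibble with `valence`, `arousal` (+/-1) per stimulus
#'   to colour the quadrants.
#' @param dims which two dimensions to display.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.indscal_solution <- function(object, labels = NULL, dims = c(1, 2),
                                      ...) {
  plot_space(object$group_space, labels, dims,
             sprintf("INDSCAL group space (stress %.3f, R2 %.3f)",
                     object$stress, object$r_squared))
}

#' @rdname autoplot.indscal_solution
#' @export
autoplot.statis_solution <- function(object, labels = NULL, dims = c(1, 2),
                                     ...) {
  plot_space(object$factor_scores, labels, dims, "STATIS compromise space")
}

plot_space <- function(space, labels, dims, title) {
  df <- tibble(d1 = space[, dims[1]], d2 = space[, dims[2]],
               stimulus = seq_len(nrow(space)))
  if (!is.null(labels)) {
    df$quadrant <- quadrant_code(labels$valence, labels$arousal)
    p <- ggplot(df, aes(.data$d1, .data$d2, colour = .data$quadrant))
  } else {
    p <- ggplot(df, aes(.data$d1, .data$d2))
  }
  p + geom_point(size = 2) +
    geom_text(aes(label = .data$stimulus), nudge_y = 0.03, size = 2.5,
              show.legend = FALSE) +
    labs(x = sprintf("dimension %d", dims[1]),
         y = sprintf("dimension %d", dims[2]), title = title) +
    theme_minimal()
}

#' @export
plot.cv_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.volume_map <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.indscal_solution <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.statis_solution <- function(x, ...) print(autoplot(x, ...))
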