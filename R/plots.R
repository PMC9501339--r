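# ggplot2 views of the package's result objects.

#' Plot a biofilm height map
#'
#' Raster view of the per-column top heights in um.
#'
#' @param object A [height_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot height_map
#' @export
autoplot.height_map <- function(object, ...) {
  d <- dim(object$h)
  df <- tibble(
    x = rep((seq_len(d[2]) - 0.5) * object$dx, each = d[1]),
    y = rep((seq_len(d[1]) - 0.5) * object$dy, times = d[2]),
    h = as.vector(object$h)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (um)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot a point pattern
#'
#' @param object A [point_pattern_2d()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot point_pattern
#' @export
autoplot.point_pattern <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, object$window[1]),
                         ylim = c(0, object$window[2])) +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot data and fitted curve of a model fit
#'
#' @param object A `biofilm_fit` from [fit_monoexponential()] or
#'   [fit_sigmoid_coverage()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot biofilm_fit
#' @export
autoplot.biofilm_fit <- function(object, ...) {
  df <- tibble(x = object$data$x, y = object$data$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point()
  if (object$converged) {
    xs <- seq(min(df$x), max(df$x), length.out = 200)
    fitdf <- tibble(x = xs,
                    y = predict_biofilm(object$model,
                                        coef_named(object$estimates), xs))
    p <- p + ggplot2::geom_line(data = fitdf, colour = "steelblue")
  }
  lab <- switch(object$model,
                monoexponential = c("biovolume V (um^3)", "roughness SR"),
                logistic = c("time (days)", "coverage fraction"))
  p + ggplot2::labs(x = lab[1], y = lab[2])
}

#' Plot a growth series
#'
#' @param object A [growth_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growth_series
#' @export
autoplot.growth_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = paste0(attr(object, "metric"),
                             if (nzchar(attr(object, "units")))
                               paste0(" (", attr(object, "units"), ")")
                             else ""))
}

#' @importFrom rlang .data
NULL
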