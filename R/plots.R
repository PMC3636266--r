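#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' metagene profiles (one line per gene group), repeat enrichment tables
#' (fold enrichment per class with the input level at 1 marked), NRL fits
#' (per-timepoint apparent NRL with the regression line extended to time 0),
#' and signal tracks (windowed values along each chromosome).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name satchrom-plots
NULL

#' @rdname satchrom-plots
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = sprintf("distance from %s (bp)", toupper(attr(object, "anchor"))),
      y = "mean signal per window", colour = "group"
    )
}

#' @rdname satchrom-plots
#' @method autoplot repeat_enrichment
#' @export
autoplot.repeat_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$class,
                                                          -.data$fold),
                                       y = .data$fold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "fold enrichment over input") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname satchrom-plots
#' @method autoplot nrl_fit
#' @export
autoplot.nrl_fit <- function(object, ...) {
  ggplot2::ggplot(object$slopes, ggplot2::aes(x = .data$time_min,
                                              y = .data$nrl_bp)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$nrl0, slope = -object$rate,
                         colour = "steelblue") +
    ggplot2::annotate("point", x = 0, y = object$nrl0, shape = 1, size = 3,
                      colour = "steelblue") +
    ggplot2::expand_limits(x = 0) +
    ggplot2::labs(x = "digestion time (min)", y = "apparent NRL (bp)")
}

#' @rdname satchrom-plots
#' @method autoplot signal_track
#' @export
autoplot.signal_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("signal (%s, %d-bp windows)",
                              track_norm(object), track_window(object)))
}
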