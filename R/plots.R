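#' Plot one read's BrdU trace with its segmentation
#'
#' Raw per-thymidine probabilities (points), the smoothed signal (line) and,
#' optionally, the fitted linear segments coloured by their B/A/P/N class.
#'
#' @param trace One row of a [trace_tbl] (or a subsetted single-read table).
#' @param params A [fork_params()] list.
#' @param show_segments Overlay the classified segments.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, params = fork_params(), show_segments = TRUE) {
  stopifnot(nrow(trace) == 1)
  sig <- trace$signal[[1]]
  sm <- smooth_trace(sig$position, sig$prob, trace$start, trace$end,
                     params = params, grid = params$grid)
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = sig, ggplot2::aes(x = .data$position, y = .data$prob),
      colour = "lightblue", size = 0.3, alpha = 0.6
    ) +
    ggplot2::labs(x = sprintf("%s position (bp)", trace$chrom),
                  y = "BrdU probability", title = trace$read_id) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (nrow(sm)) {
    p <- p + ggplot2::geom_line(
      data = sm, ggplot2::aes(x = .data$position, y = .data$value),
      colour = "steelblue"
    )
    if (show_segments) {
      seg <- segment_trace(sm, params)
      if (nrow(seg)) {
        p <- p + ggplot2::geom_segment(
          data = seg,
          ggplot2::aes(x = .data$x_start, xend = .data$x_end,
                       y = .data$y_start, yend = .data$y_end,
                       colour = .data$label),
          linewidth = 1
        ) +
          ggplot2::scale_colour_manual(
            values = c(B = "grey40", A = "goldenrod", P = "forestgreen",
                       N = "firebrick"),
            name = "segment"
          )
      }
    }
  }
  p
}

#' @describeIn call_forks Density of measured fork speeds with the median
#'   and 50%/95% intervals, one panel per sample when several are present.
#' @param object A `fork_calls` object.
#' @export
autoplot.fork_calls <- function(object, ...) {
  fk <- object$forks
  stopifnot(nrow(fk) > 0)
  med <- stats::median(fk$speed)
  ggplot2::ggplot(fk, ggplot2::aes(x = .data$speed)) +
    ggplot2::geom_density(fill = "thistle", colour = "purple4",
                          alpha = 0.6) +
    ggplot2::geom_vline(xintercept = med, colour = "grey30",
                        linetype = "dashed") +
    ggplot2::labs(x = "fork speed (bp/min)", y = "density",
                  subtitle = sprintf("n = %d, median = %.0f bp/min",
                                     nrow(fk), med)) +
    ggplot2::theme_minimal()
}

#' @describeIn deconvolve_speeds Discrete deconvolved weights (columns) with
#'   the continuous mixture fit (line).
#' @param object A `speed_deconv` object.
#' @export
autoplot.speed_deconv <- function(object, ...) {
  w <- object$weights
  grid <- seq(1, max(w$center) + 100, by = 10)
  dens <- mixture_density(object$mixture, grid)
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = w, ggplot2::aes(x = .data$center, y = .data$weight / 100),
      fill = "palegreen3", alpha = 0.7, width = 90
    ) +
    ggplot2::geom_line(
      data = tibble::tibble(x = grid, y = dens),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "darkgreen"
    ) +
    ggplot2::labs(x = "true fork speed (bp/min)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a replication fork directionality track
#'
#' @param object An `rfd_track` tibble from [compute_rfd()].
#' @param ... Unused.
#' @return A ggplot object (one facet per chromosome).
#' @export
autoplot.rfd_track <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$rfd), ],
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$rfd)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "position (bp)", y = "RFD") +
    ggplot2::theme_minimal()
}

#' Plot a multi-scale speed map
#'
#' Median fork speed per window with its 98% CI ribbon at the largest width,
#' and significance tiles across widths.
#'
#' @param object A `speed_map` tibble from [speed_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.speed_map <- function(object, ...) {
  wmax <- max(object$width)
  top <- object[object$width == wmax & !is.na(object$median_speed), ]
  ggplot2::ggplot(top, ggplot2::aes(x = (.data$start + .data$end) / 2)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "lightblue", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_speed),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "median fork speed (bp/min)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
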