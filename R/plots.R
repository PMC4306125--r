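#' Plot segmental strain or strain-rate curves
#'
#' One colored curve per AHA segment plus the global mean in black,
#' mirroring the usual per-level strain panels.
#'
#' @param curves tibble from [segment_curves()].
#' @param what `"strain"` (radial strain, percent) or `"strain_rate"`
#'   (1/s).
#' @return A ggplot object.
#' @export
plot_segment_curves <- function(curves, what = c("strain", "strain_rate")) {
  what <- match.arg(what)
  ycol <- if (what == "strain") "radial_strain_pct" else "radial_strain_rate_per_s"
  ylab <- if (what == "strain") "radial strain (%)" else "radial strain rate (1/s)"
  seg <- curves[curves$segment_id != 0L, ]
  glob <- curves[curves$segment_id == 0L, ]
  ggplot2::ggplot(seg, ggplot2::aes(x = time_ms, y = .data[[ycol]],
                                    color = factor(segment_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = glob, color = "black", linewidth = 1) +
    ggplot2::labs(x = "time (ms)", y = ylab, color = "segment",
                  title = sprintf("%s level", unique(curves$level)[1])) +
    ggplot2::theme_minimal()
}

#' Quiver plot of a displacement field
#'
#' @param field a [displacement_field()].
#' @param step subsampling stride in pixels.
#' @param scale arrow length multiplier.
#' @return A ggplot object.
#' @export
plot_displacement_field <- function(field, step = 4L, scale = 1) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(field$u)
  ys <- seq(1L, d[1], by = step); xs <- seq(1L, d[2], by = step)
  df <- expand.grid(row = ys, col = xs)
  df$x <- df$col - 1L; df$y <- df$row - 1L
  df$ux <- field$u[, , 1][cbind(df$row, df$col)]
  df$uy <- field$u[, , 2][cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   xend = x + scale * ux,
                                   yend = y + scale * uy)) +
    ggplot2::geom_segment(linewidth = 0.3,
                          arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d displacement (px)", field$frame),
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
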