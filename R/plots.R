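# Simple base-graphics views of the spatial objects.

#' Plot a kernel home range
#'
#' Draws the 90% (or configured) utilization contour, optionally over the
#' fixes it was estimated from.
#'
#' @param x A [home_range_kde()] object.
#' @param fixes Optional two-column matrix/data frame of fix coordinates.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.home_range <- function(x, fixes = NULL, ...) {
  xr <- range(x$xs); yr <- range(x$ys)
  graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (m)",
                 ylab = "y (m)",
                 main = sprintf("%.0f%% kernel home range", 100 * x$level), ...)
  if (!is.null(fixes))
    graphics::points(fixes[, 1], fixes[, 2], pch = 16, cex = 0.2,
                     col = grDevices::grey(0.6))
  for (ct in x$contours) graphics::lines(ct, col = "darkgreen", lwd = 2)
  invisible(x)
}

#' Plot derived villages
#'
#' Village outlines (contours of the closed building clusters) with their
#' areas.
#'
#' @param x A [derive_villages()] object.
#' @param add Add to an existing plot instead of opening one.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.villages <- function(x, add = FALSE, ...) {
  if (!x$n) {
    warning("no villages to plot")
    return(invisible(x))
  }
  if (!add) {
    xr <- c(x$x0, x$x0 + nrow(x$labels) * x$res)
    yr <- c(x$y0, x$y0 + ncol(x$labels) * x$res)
    graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (m)",
                   ylab = "y (m)", main = "Derived villages", ...)
  }
  for (p in x$polygons) graphics::polygon(p, border = "grey30",
                                          col = grDevices::grey(0.85))
  invisible(x)
}

#' Map a pipeline's resting sites over the landscape
#'
#' Villages, filtered roads, vegetation patches, and the clustered
#' resting sites scaled by visit count - the study-at-a-glance figure.
#'
#' @param x A [run_pipeline()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.restsel_pipeline <- function(x, ...) {
  ext <- x$study$landscape$extent
  graphics::plot(NA, xlim = c(0, ext), ylim = c(0, ext), asp = 1,
                 xlab = "x (m)", ylab = "y (m)",
                 main = "Resting sites over the landscape", ...)
  for (p in x$study$landscape$vegetation)
    graphics::polygon(p, border = NA, col = grDevices::adjustcolor("darkgreen", 0.15))
  for (r in suppressMessages(filter_roads(x$study$landscape$roads)))
    graphics::lines(r$coords, col = "tan4", lwd = 1.5)
  plot(x$study$villages, add = TRUE)
  graphics::points(x$sites$x, x$sites$y, pch = 21, bg = "orangered",
                   cex = 0.5 + sqrt(x$sites$n_visits) / 2)
  invisible(x)
}
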