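#' Plot a fitted slide: response curve and residuals
#'
#' Two base-graphics panels: all spots plotted as intensity against their
#' estimated effective log2 concentration (`x_i + d_j`) with the shared
#' fitted curve overlaid, and per-spot residuals against the same axis.
#' Useful for spotting outlier series before choosing exclusions.
#'
#' @param x an `rppa_supercurve`.
#' @param main title prefix (typically the antibody name).
#' @param ... ignored.
#' @return Invisibly, `x`.
#' @export
plot.rppa_supercurve <- function(x, main = "", ...) {
  res <- x$residuals
  est <- x$estimates
  xi <- est$x[match(res$series_id, est$series_id)]
  xx <- xi + res$d
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))

  graphics::plot(xx, res$observed, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4),
                 xlab = "estimated log2 concentration",
                 ylab = "net intensity",
                 main = sprintf("%s fitted response (R2 = %.4f)", main,
                                x$fit$r2))
  grid_x <- seq(min(xx), max(xx), length.out = 200)
  graphics::lines(grid_x, response(grid_x, x$fit), col = "firebrick", lwd = 2)

  graphics::plot(xx, res$residual, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4),
                 xlab = "estimated log2 concentration", ylab = "residual",
                 main = "residuals")
  graphics::abline(h = 0, col = "firebrick")
  invisible(x)
}
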