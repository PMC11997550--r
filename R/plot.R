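# Trajectory plotting: the four-panel state layout plus the ROS/expulsion
# panel with the bleaching threshold drawn.

#' Plot a model trajectory
#'
#' Draws any subset of five panels: `"reserves"` (areal reserves and
#' biomass), `"normalised"` (normalised internal reserves), `"pigments"`
#' (chlorophyll a and the two xanthophylls), `"rc"` (reaction-centre state
#' fractions) and `"ros"` (per-cell ROS with the bleaching threshold line
#' and the expulsion rate). Daily tick marks sit at 0:00 h.
#'
#' @param x a `cbm_trajectory`.
#' @param panels character vector of panel names (default: all five).
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.cbm_trajectory <- function(x, panels = c("reserves", "normalised",
                                              "pigments", "rc", "ros"),
                                ...) {
  panels <- match.arg(panels, several.ok = TRUE)
  if (!length(panels)) return(invisible(x))
  p <- attr(x, "params")
  th <- p$photo$ros_threshold
  tt <- x$time_days
  ticks <- seq(floor(min(tt)), ceiling(max(tt)), by = 1)
  op <- graphics::par(mfrow = c(length(panels), 1),
                      mar = c(2.5, 4, 1.5, 1), mgp = c(2.2, 0.6, 0))
  on.exit(graphics::par(op))
  ax <- function() graphics::axis(1, at = ticks)
  for (pn in panels) {
    switch(pn,
      reserves = {
        ylim <- range(0, x$cs, x$r_n, x$r_c, x$r_p)
        graphics::plot(tt, x$cs, type = "l", ylim = ylim, xaxt = "n",
                       xlab = "", ylab = "mg m-2", main = "Reserves & biomass")
        graphics::lines(tt, x$r_n, col = "blue")
        graphics::lines(tt, x$r_c, col = "darkgreen")
        graphics::lines(tt, x$r_p, col = "orange")
        graphics::legend("topleft", bty = "n", lty = 1, cex = 0.8,
                         col = c("black", "blue", "darkgreen", "orange"),
                         legend = c("biomass CS", "R_N", "R_C", "R_P"))
        ax()
      },
      normalised = {
        graphics::plot(tt, x$rn_norm, type = "l", ylim = c(0, 1), col = "blue",
                       xaxt = "n", xlab = "", ylab = "normalised",
                       main = "Normalised internal reserves")
        graphics::lines(tt, x$rc_norm, col = "darkgreen")
        graphics::lines(tt, x$rp_norm, col = "orange")
        graphics::legend("topleft", bty = "n", lty = 1, cex = 0.8,
                         col = c("blue", "darkgreen", "orange"),
                         legend = c("R_N*", "R_C*", "R_P*"))
        ax()
      },
      pigments = {
        ylim <- range(0, x$chl, x$x_p, x$x_h)
        graphics::plot(tt, x$chl, type = "l", ylim = ylim, col = "darkgreen",
                       xaxt = "n", xlab = "", ylab = "mg m-2",
                       main = "Pigments")
        graphics::lines(tt, x$x_p, col = "goldenrod")
        graphics::lines(tt, x$x_h, col = "brown")
        graphics::legend("topleft", bty = "n", lty = 1, cex = 0.8,
                         col = c("darkgreen", "goldenrod", "brown"),
                         legend = c("Chl a", "X_p (photosynthetic)",
                                    "X_h (photoprotective)"))
        ax()
      },
      rc = {
        graphics::plot(tt, x$q_ox_frac, type = "l", ylim = c(0, 1),
                       col = "forestgreen", xaxt = "n", xlab = "",
                       ylab = "fraction", main = "Reaction-centre states")
        graphics::lines(tt, x$q_red_frac, col = "steelblue")
        graphics::lines(tt, x$q_in_frac, col = "firebrick")
        graphics::legend("topleft", bty = "n", lty = 1, cex = 0.8,
                         col = c("forestgreen", "steelblue", "firebrick"),
                         legend = c("oxidised", "reduced", "inhibited"))
        ax()
      },
      ros = {
        ylim <- range(0, x$ros_percell, th * 1.1)
        graphics::plot(tt, x$ros_percell, type = "l", ylim = ylim,
                       xaxt = "n", xlab = "time (days)",
                       ylab = "mg O cell-1", main = "Per-cell ROS & expulsion")
        graphics::abline(h = th, lty = 2, col = "red")
        graphics::mtext(sprintf("threshold %.3g", th), side = 4, cex = 0.6)
        if (any(x$expulsion > 0)) {
          sc <- ylim[2] / max(x$expulsion)
          graphics::lines(tt, x$expulsion * sc, col = "purple", lty = 3)
        }
        ax()
      })
  }
  invisible(x)
}
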