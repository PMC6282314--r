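# Base-graphics diagnostics.

#' Plot an alpha curve
#'
#' Alpha-shape volume (as % of raw voxel volume) against refinement
#' coefficient on a log axis, with the 100% line whose crossing defines the
#' optimal refinement and an asterisk at the breakdown coefficient.
#'
#' @param x an [alpha_curve()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.alpha_curve <- function(x, ...) {
  graphics::plot(x$k, x$volume_pct_raw, log = "x", type = "l",
                 xlab = "refinement coefficient k",
                 ylab = "alpha volume (% of raw volume)", ...)
  graphics::abline(h = 100, lty = 2, col = "grey40")
  kb <- breakdown_k(x)
  if (!is.na(kb)) {
    yb <- x$volume_pct_raw[which.min(abs(x$k - kb))]
    graphics::points(kb, yb, pch = 8, col = "red")
  }
  invisible(x)
}

#' Plot box counts and local slopes
#'
#' Left: `log N(s)` against `log(1/s)` with the fitted slope; right: local
#' slopes between successive box sizes (a plateau across several sizes is
#' the signature of genuine fractal scaling).
#'
#' @param x a [box_count()] result.
#' @param fit a [fractal_dimension()] result (recomputed if missing).
#' @param ... passed to [graphics::plot()].
#' @export
plot.box_counts <- function(x, fit = NULL, ...) {
  if (is.null(fit)) fit <- fractal_dimension(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log(1 / x$s), log(x$N), xlab = "log(1/s)", ylab = "log N(s)",
                 ...)
  graphics::abline(stats::lm(log(x$N) ~ log(1 / x$s)), col = "grey40")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("FD = %.3f", fit$fd_slope))
  mids <- sqrt(head(x$s, -1) * x$s[-1])
  graphics::plot(mids, fit$local_slopes, log = "x", type = "b",
                 xlab = "box size s", ylab = "local slope")
  invisible(x)
}
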