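#' Plot DOC or hydrate-saturation profiles through time
#'
#' Base-graphics depth profiles of a run at its snapshot times, colored from
#' early (light) to late (dark). Presentation helper only.
#'
#' @param result an [run_scenario()] result.
#' @param what `"doc"` (H + L, mM), `"sh"` (hydrate saturation) or `"poc"`.
#' @param times optional subset of snapshot times to draw (years; nearest).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix (depth x time).
#' @export
plot_profiles <- function(result, what = c("doc", "sh", "poc"), times = NULL, ...) {
  what <- match.arg(what)
  col <- result$scenario$column
  snaps <- result$snapshots
  if (!is.null(times)) {
    ts <- vapply(snaps, function(s) s$t, 0)
    snaps <- snaps[unique(vapply(times, function(tt) which.min(abs(ts - tt)), 0L))]
  }
  f <- switch(what, doc = function(s) s$H + s$L, sh = function(s) s$S,
              poc = function(s) s$P)
  m <- vapply(snaps, f, numeric(length(col$node_depths)))
  lab <- switch(what, doc = "DOC (mM)", sh = expression(S[H]), poc = "POC (mM)")
  shade <- grDevices::gray(seq(0.8, 0, length.out = max(ncol(m), 2)))
  graphics::matplot(m, col$node_depths, type = "l", lty = 1, col = shade,
                    ylim = rev(range(col$node_depths)),
                    xlab = lab, ylab = "depth in interval (m)", ...)
  sand <- range(col$node_depths[col$lithology == "sand"])
  graphics::abline(h = sand, lty = 3)
  invisible(m)
}

#' Image plot of a sweep metric with the constraint region overlaid
#'
#' @param result a [run_sweep()] result.
#' @param metric metric column to display.
#' @param region optional [constraint_region()] whose boundary is overlaid.
#' @param ... passed to [graphics::image()].
#' @export
plot_sweep <- function(result, metric = "max_SH_sand", region = NULL, ...) {
  spec <- attr(result, "spec")
  z <- matrix(result[[metric]], nrow = length(spec$keh), ncol = length(spec$kfm))
  graphics::image(spec$keh, spec$kfm, z,
                  xlab = expression(log[10] ~ K[eh]),
                  ylab = expression(log[10] ~ K[fm]), ...)
  if (!is.null(region) && nrow(region$boundary))
    graphics::segments(region$boundary$x0, region$boundary$y0,
                       region$boundary$x1, region$boundary$y1, lty = 2, col = "red")
  invisible(z)
}
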