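#' Plot aggregate recruitment curves
#'
#' Mean +/- SEM over time for one or more conditions, drawn with base
#' graphics (error bars as vertical segments).
#'
#' @param aggs a single [aggregate_curves()] result or a named list of
#'   them.
#' @param path optional PNG output path; when given the plot is written
#'   there instead of the active device.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_aggregate <- function(aggs, path = NULL, main = "Stripe recruitment") {
  if (inherits(aggs, "aggregate_curve")) aggs <- list(aggs)
  if (is.null(names(aggs)) || any(!nzchar(names(aggs))))
    names(aggs) <- vapply(seq_along(aggs), function(i) {
      cond <- attr(aggs[[i]], "condition")
      if (nzchar(cond)) cond else paste0("condition", i)
    }, "")
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  ylim <- range(unlist(lapply(aggs, function(a) c(a$mean_sx - a$sem,
                                                  a$mean_sx + a$sem))))
  xlim <- range(unlist(lapply(aggs, `[[`, "t_s")))
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "time (s)",
                 ylab = "relative stripe brightness Sx", main = main)
  graphics::abline(h = 1, lty = 3, col = "grey60")
  for (i in seq_along(aggs)) {
    a <- aggs[[i]]
    graphics::lines(a$t_s, a$mean_sx, col = i, lwd = 2)
    graphics::points(a$t_s, a$mean_sx, col = i, pch = 16)
    graphics::segments(a$t_s, a$mean_sx - a$sem, a$t_s, a$mean_sx + a$sem,
                       col = i)
  }
  graphics::legend("topleft", legend = names(aggs), col = seq_along(aggs),
                   lwd = 2, bty = "n")
  invisible(path)
}

#' Plot clonogenic survival curves
#'
#' Surviving fraction (log scale) versus dose with error bars, one color
#' per condition.
#'
#' @param curve a [surviving_fraction()] result (may hold several
#'   conditions).
#' @param path optional PNG output path.
#' @param xlab x-axis label (dose units are agent-specific).
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_survival <- function(curve, path = NULL, xlab = "dose") {
  stopifnot(inherits(curve, "survival_curve"))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  conds <- unique(curve$condition)
  lo <- pmax(curve$mean_sf - ifelse(is.na(curve$err), 0, curve$err), 1e-4)
  graphics::plot(NA, xlim = range(curve$dose),
                 ylim = range(c(lo, curve$mean_sf + ifelse(is.na(curve$err), 0, curve$err))),
                 log = "y", xlab = xlab, ylab = "surviving fraction")
  for (i in seq_along(conds)) {
    g <- curve[curve$condition == conds[i], ]
    graphics::lines(g$dose, g$mean_sf, col = i, lwd = 2)
    graphics::points(g$dose, g$mean_sf, col = i, pch = 16)
    ok <- !is.na(g$err)
    graphics::segments(g$dose[ok], pmax(g$mean_sf[ok] - g$err[ok], 1e-4),
                       g$dose[ok], g$mean_sf[ok] + g$err[ok], col = i)
  }
  graphics::legend("bottomleft", legend = conds, col = seq_along(conds),
                   lwd = 2, bty = "n")
  invisible(path)
}
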