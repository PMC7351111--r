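#' Relative stripe brightness Sx
#'
#' The per-cell, per-frame statistic of the stripe-recruitment assay:
#' \deqn{S_x = (A_x - B) / (C_x - B)}
#' where `Ax` is the mean stripe intensity, `Cx` the mean intensity of the
#' rest of the nucleus (selected avoiding the stripe) and `B` the mean
#' background of the field of view. Sx = 1 means no enrichment at the
#' stripe. The ratio is invariant to any affine intensity transform
#' (gain and offset) applied to the whole frame, which is what makes it
#' robust to photobleaching and illumination drift.
#'
#' A cell whose nucleus is not brighter than the background (`Cx <= B`)
#' has no meaningful contrast; this is an error rather than an unstable
#' ratio.
#'
#' @param ax,cx,b numeric vectors (recycled): mean stripe,
#'   nucleus-remainder and background intensities.
#' @param cell_id,frame optional identifiers used in error messages.
#' @return numeric vector of Sx values.
#' @examples
#' compute_sx(1.5, 1.0, 0.5)  # 2
#' @export
compute_sx <- function(ax, cx, b, cell_id = NULL, frame = NULL) {
  bad <- which(cx <= b)
  if (length(bad) > 0L) {
    who <- if (!is.null(cell_id))
      sprintf(" (cell %s, frame %s)", cell_id[bad[1]],
              if (!is.null(frame)) frame[bad[1]] else "?")
    else ""
    stopf("degenerate contrast: Cx <= B%s", who)
  }
  (ax - b) / (cx - b)
}

#' Per-cell recruitment curves from ROI measurements
#'
#' Applies [compute_sx()] to every row of a measurement table (as produced
#' by [measure_rois()]).
#'
#' @param measurements data.frame with columns `cell_id`, `frame`, `t_s`,
#'   `Ax`, `Cx`, `B`.
#' @return data.frame with columns `cell_id`, `frame`, `t_s`, `sx`.
#' @export
sx_curves <- function(measurements) {
  m <- measurements
  stopifnot(all(c("cell_id", "frame", "t_s", "Ax", "Cx", "B") %in% names(m)))
  data.frame(cell_id = m$cell_id, frame = m$frame, t_s = m$t_s,
             sx = compute_sx(m$Ax, m$Cx, m$B, m$cell_id, m$frame),
             stringsAsFactors = FALSE)
}

#' Aggregate per-cell curves into a mean +/- SEM curve
#'
#' Per timepoint, the cross-cell mean Sx and its standard error (sample
#' standard deviation divided by the square root of the number of cells),
#' with the number of cells recorded. All cells must share the same
#' timepoint grid and there must be at least two of them (SEM is undefined
#' otherwise).
#'
#' @param curves per-cell curves from [sx_curves()].
#' @param condition free-text condition label.
#' @param pre_frame index (1-based, on the sorted timepoint grid) of the
#'   pre-irradiation frame; the first frame by default.
#' @return a data.frame of class `aggregate_curve` with columns `t_s`,
#'   `mean_sx`, `sem`, `n`, and attributes `condition`, `pre_frame`,
#'   `offset` (cumulative normalization offset, 0 until
#'   [normalize_to_t0()] is applied) and `normalized`.
#' @export
aggregate_curves <- function(curves, condition = "", pre_frame = 1L) {
  stopifnot(all(c("cell_id", "t_s", "sx") %in% names(curves)))
  cells <- unique(curves$cell_id)
  if (length(cells) < 2L) stopf("need >= 2 cells (SEM undefined for n < 2)")
  grids <- split(curves$t_s, curves$cell_id)
  ref <- sort(grids[[1]])
  for (g in grids) if (!isTRUE(all.equal(sort(g), ref)))
    stopf("cells do not share a common timepoint grid")
  if (pre_frame < 1L || pre_frame > length(ref))
    stopf("pre-irradiation frame index %d outside the %d-point grid",
          pre_frame, length(ref))
  sx_by_t <- split(curves$sx, factor(curves$t_s, levels = ref))
  out <- data.frame(t_s = ref,
                    mean_sx = vapply(sx_by_t, mean, 0),
                    sem = vapply(sx_by_t, sem, 0),
                    n = vapply(sx_by_t, length, 0L),
                    row.names = NULL)
  structure(out, condition = condition, pre_frame = as.integer(pre_frame),
            offset = 0, normalized = FALSE,
            class = c("aggregate_curve", "data.frame"))
}

#' Normalize an aggregate curve to the pre-irradiation frame
#'
#' Additive normalization: the offset `delta = mean(t_pre) - 1` is
#' subtracted from the mean at every timepoint, so the pre-irradiation
#' mean becomes exactly 1 (e.g. a pre-irradiation mean of 1.12 has 0.12
#' subtracted from this and all later timepoints; a mean of 0.9 has 0.1
#' added). SEM values are unchanged — an additive shift does not alter
#' dispersion. The operation is idempotent; the cumulative offset is kept
#' in the `offset` attribute.
#'
#' @param agg an [aggregate_curves()] result.
#' @return the normalized `aggregate_curve`.
#' @export
normalize_to_t0 <- function(agg) {
  stopifnot(inherits(agg, "aggregate_curve"))
  pre <- attr(agg, "pre_frame")
  if (is.null(pre) || pre < 1L || pre > nrow(agg))
    stopf("missing pre-irradiation frame")
  delta <- agg$mean_sx[pre] - 1
  agg$mean_sx <- agg$mean_sx - delta
  attr(agg, "offset") <- attr(agg, "offset") + delta
  attr(agg, "normalized") <- TRUE
  agg
}

#' @export
print.aggregate_curve <- function(x, ...) {
  cat(sprintf("<aggregate_curve> %s%d timepoints, n = %s cells%s\n",
              if (nzchar(attr(x, "condition")))
                paste0(attr(x, "condition"), ": ") else "",
              nrow(x), paste(unique(x$n), collapse = "/"),
              if (isTRUE(attr(x, "normalized")))
                sprintf(", normalized (offset %.4g)", attr(x, "offset")) else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Compare two conditions per timepoint
#'
#' Two-sample two-tailed Student's t test (equal-variance by default,
#' Welch behind the `var_equal` flag) on the per-cell Sx values at each
#' shared timepoint, with the conventional significance tiers: `*` p <
#' 0.05, `**` p < 0.01, `***` p < 0.001, `ns` otherwise. No multiple-
#' testing correction is applied across timepoints. Two groups with zero
#' variance and equal means give p = 1 by convention.
#'
#' @param curves_a,curves_b per-cell curves ([sx_curves()]) for the two
#'   conditions; both need >= 2 cells and a common timepoint grid.
#' @param var_equal classical pooled-variance Student t (`TRUE`, default)
#'   or Welch (`FALSE`).
#' @return data.frame with columns `t_s`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`, `p`, `tier`.
#' @export
compare_conditions <- function(curves_a, curves_b, var_equal = TRUE) {
  ta <- sort(unique(curves_a$t_s)); tb <- sort(unique(curves_b$t_s))
  if (!isTRUE(all.equal(ta, tb)))
    stopf("the two conditions do not share a timepoint grid")
  out <- lapply(ta, function(t) {
    xa <- curves_a$sx[curves_a$t_s == t]
    xb <- curves_b$sx[curves_b$t_s == t]
    p <- student_t_p(xa, xb, var_equal = var_equal)
    data.frame(t_s = t, mean_a = mean(xa), mean_b = mean(xb),
               n_a = length(xa), n_b = length(xb), p = p,
               tier = significance_tier(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Estimate the recruitment plateau from a normalized aggregate curve
#'
#' Fits `S(t) = 1 + A (1 - exp(-k (t - t_lag)))` to the post-irradiation
#' part of a (normalized) aggregate curve by nonlinear least squares and
#' returns the plateau amplitude A. If the fit fails to converge, the mean
#' of the last three timepoints minus 1 is used instead (adequate once
#' `k t >> 1`).
#'
#' @param agg an [aggregate_curves()] result (normalize first).
#' @param t_lag fixed lag used in the fit, seconds.
#' @return list with `a_hat`, `k_hat` (NA for the tail fallback) and
#'   `method` (`"nls"` or `"tail"`).
#' @export
fit_plateau <- function(agg, t_lag = 0) {
  stopifnot(inherits(agg, "aggregate_curve"))
  post <- agg[agg$t_s > 0, , drop = FALSE]
  if (nrow(post) < 3L) stopf("need >= 3 post-irradiation timepoints")
  a0 <- max(post$mean_sx) - 1
  fit <- tryCatch(
    stats::nls(mean_sx ~ 1 + A * (1 - exp(-k * (t_s - t_lag))),
               data = post, start = list(A = max(a0, 0.1), k = 0.02)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tail_n <- min(3L, nrow(post))
    a_hat <- mean(utils::tail(post$mean_sx, tail_n)) - 1
    return(list(a_hat = a_hat, k_hat = NA_real_, method = "tail"))
  }
  co <- stats::coef(fit)
  list(a_hat = unname(co["A"]), k_hat = unname(co["k"]), method = "nls")
}
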