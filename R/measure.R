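#' Measure mean ROI intensities per cell and frame
#'
#' For every cell and frame, computes the arithmetic mean of the pixel
#' intensities whose centers fall inside the stripe polygon (`Ax`), the
#' nucleus-remainder polygon (`Cx`), and the shared background polygon
#' (`B`). This is the per-frame measurement step of the stripe-recruitment
#' assay; downstream, [compute_sx()] turns each (Ax, Cx, B) triplet into
#' the relative stripe brightness.
#'
#' If the stack carries z planes (`z = TRUE`) a maximum-intensity
#' projection is applied first and a single "frame" is measured.
#'
#' @param stack an [image_stack()].
#' @param rois a [roi_set()] with one polygon set per frame of `stack`.
#' @return a data.frame with columns `cell_id`, `frame` (1-based), `t_s`,
#'   `Ax`, `Cx`, `B`.
#' @export
measure_rois <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"), inherits(rois, "roi_set"))
  if (stack$z) {
    stack <- image_stack(list(max_project(stack)), stack$timestamps[1],
                         channel = stack$channel)
  }
  d <- dim_stack(stack)
  if (rois$n_frames > d[3])
    stopf("ROI set references frame %d but stack has %d frames",
          rois$n_frames, d[3])
  poly_mean <- function(frame_mat, poly, what, fidx) {
    px <- raster_pixels(poly)
    if (length(px$x) == 0L) stopf("empty ROI: %s", what)
    if (any(px$x < 0 | px$x >= d[2] | px$y < 0 | px$y >= d[1]))
      stopf("%s extends outside the %dx%d frame (frame %d)", what, d[2], d[1], fidx)
    mean(frame_mat[cbind(px$y + 1L, px$x + 1L)])
  }
  out <- vector("list", length(rois$cells) * rois$n_frames)
  k <- 0L
  for (f in seq_len(rois$n_frames)) {
    fr_mat <- stack$frames[[f]]
    b <- poly_mean(fr_mat, rois$background[[f]],
                   sprintf("background frame %d", f), f)
    for (cid in names(rois$cells)) {
      cf <- rois$cells[[cid]][[f]]
      k <- k + 1L
      out[[k]] <- data.frame(
        cell_id = cid, frame = f, t_s = stack$timestamps[f],
        Ax = poly_mean(fr_mat, cf$stripe, sprintf("stripe of %s", cid), f),
        Cx = poly_mean(fr_mat, cf$nucleus, sprintf("nucleus of %s", cid), f),
        B = b, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Propagate first-frame ROIs across a time-lapse
#'
#' Substitutes for manual per-frame re-selection when cells migrate during
#' long acquisitions. Method `"none"` copies the first-frame polygons to
#' every frame. Method `"xcorr"` estimates, per cell, an integer (dx, dy)
#' shift between consecutive frames by maximizing the normalized
#' cross-correlation of the nucleus neighborhood, and translates the
#' polygons by the cumulative shift. An ambiguous correlation peak (tie)
#' falls back to zero shift with a warning.
#'
#' @param stack an [image_stack()].
#' @param rois_at_t0 a [roi_set()] with `n_frames == 1`.
#' @param method `"none"` or `"xcorr"`.
#' @param search maximum per-frame shift searched, in pixels.
#' @return a [roi_set()] with one polygon set per frame of `stack`.
#' @export
track_rois <- function(stack, rois_at_t0, method = c("none", "xcorr"),
                       search = 8L) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"), inherits(rois_at_t0, "roi_set"),
            rois_at_t0$n_frames == 1L)
  n <- dim_stack(stack)[3]
  h <- dim_stack(stack)[1]; w <- dim_stack(stack)[2]

  if (method == "none") {
    return(roi_set(
      cells = lapply(rois_at_t0$cells, function(cf) rep(cf[1], n)),
      background = rep(rois_at_t0$background[1], n), validate = FALSE))
  }

  crop <- function(mat, x0, x1, y0, y1) {
    mat[pmax(1L, y0 + 1L):pmin(h, y1 + 1L), pmax(1L, x0 + 1L):pmin(w, x1 + 1L)]
  }
  cells_out <- list()
  for (cid in names(rois_at_t0$cells)) {
    base <- rois_at_t0$cells[[cid]][[1]]
    bbox <- apply(rbind(base$stripe, base$nucleus), 2, range)
    sx <- 0L; sy <- 0L
    frames_out <- vector("list", n)
    frames_out[[1]] <- base
    for (f in seq_len(n)[-1]) {
      x0 <- floor(bbox[1, 1]) + sx; x1 <- ceiling(bbox[2, 1]) + sx
      y0 <- floor(bbox[1, 2]) + sy; y1 <- ceiling(bbox[2, 2]) + sy
      m <- search + 1L
      if (x0 - m < 0 || y0 - m < 0 || x1 + m > w - 1 || y1 + m > h - 1)
        stopf("tracking window for cell %s leaves the image at frame %d", cid, f)
      ref <- crop(stack$frames[[f - 1L]], x0, x1, y0, y1)
      shifts <- expand.grid(dx = -search:search, dy = -search:search)
      score <- vapply(seq_len(nrow(shifts)), function(i) {
        cur <- crop(stack$frames[[f]], x0 + shifts$dx[i], x1 + shifts$dx[i],
                    y0 + shifts$dy[i], y1 + shifts$dy[i])
        if (stats::sd(cur) == 0 || stats::sd(ref) == 0) return(-Inf)
        stats::cor(as.vector(ref), as.vector(cur))
      }, 0)
      best <- which(score >= max(score) - 1e-12)
      if (length(best) > 1L || !is.finite(max(score))) {
        warnf("ambiguous correlation peak for cell %s at frame %d; using zero shift",
              cid, f)
        dx <- 0L; dy <- 0L
      } else {
        dx <- shifts$dx[best]; dy <- shifts$dy[best]
      }
      sx <- sx + dx; sy <- sy + dy
      frames_out[[f]] <- list(stripe = translate_polygon(base$stripe, sx, sy),
                              nucleus = translate_polygon(base$nucleus, sx, sy))
    }
    cells_out[[cid]] <- frames_out
  }
  roi_set(cells = cells_out, background = rep(rois_at_t0$background[1], n),
          validate = FALSE)
}
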