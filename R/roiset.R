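#' Per-cell, per-frame region-of-interest set
#'
#' Holds, for every cell and frame, the hand-drawn (or simulated) stripe
#' polygon and nucleus-remainder polygon, plus one background polygon per
#' frame that is shared by all cells in the field of view. The stripe and
#' nucleus-remainder polygons of a cell must be disjoint (the nucleus
#' region is selected avoiding the irradiated stripe) and every polygon
#' must cover at least one pixel center.
#'
#' @param cells named list; one element per cell id, each a list with one
#'   entry per frame, each entry a `list(stripe = , nucleus = )` of n x 2
#'   polygon vertex matrices.
#' @param background list with one polygon per frame (the field background,
#'   shared across cells).
#' @param validate check the disjointness / non-empty invariants (set to
#'   `FALSE` for speed when the polygons come from the simulator).
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(cells, background, validate = TRUE) {
  stopifnot(is.list(cells), length(cells) >= 1L, !is.null(names(cells)),
            is.list(background))
  n_frames <- length(background)
  cells <- lapply(cells, function(cf) {
    if (length(cf) != n_frames)
      stopf("each cell needs one stripe/nucleus polygon pair per frame")
    lapply(cf, function(fr) list(stripe = as_polygon(fr$stripe),
                                 nucleus = as_polygon(fr$nucleus)))
  })
  background <- lapply(background, as_polygon)
  out <- structure(list(cells = cells, background = background,
                        n_frames = n_frames), class = "roi_set")
  if (validate) validate_roi_set(out)
  out
}

# Invariant checks: every polygon rasterizes to >= 1 pixel (over its own
# bounding box) and stripe/nucleus-remainder are pixel-disjoint.
validate_roi_set <- function(rois) {
  check_nonempty <- function(poly, what) {
    if (length(raster_pixels(poly)$x) == 0L)
      stopf("empty ROI: %s rasterizes to 0 pixels", what)
  }
  for (cid in names(rois$cells)) {
    for (f in seq_len(rois$n_frames)) {
      fr <- rois$cells[[cid]][[f]]
      check_nonempty(fr$stripe, sprintf("stripe of cell %s frame %d", cid, f))
      check_nonempty(fr$nucleus, sprintf("nucleus of cell %s frame %d", cid, f))
      sp <- raster_pixels(fr$stripe)
      if (any(points_in_polygon(sp$x, sp$y, fr$nucleus)))
        stopf("stripe and nucleus-remainder polygons overlap for cell %s frame %d",
              cid, f)
    }
  }
  for (f in seq_along(rois$background))
    check_nonempty(rois$background[[f]], sprintf("background frame %d", f))
  invisible(rois)
}

# Pixel centers covered by a polygon, in absolute 0-based coordinates
# (unclipped by any image boundary).
raster_pixels <- function(poly) {
  poly <- as_polygon(poly)
  xs <- ceiling(min(poly[, 1]) - 1e-9):floor(max(poly[, 1]) + 1e-9)
  ys <- ceiling(min(poly[, 2]) - 1e-9):floor(max(poly[, 2]) + 1e-9)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  keep <- points_in_polygon(px, py, poly)
  list(x = px[keep], y = py[keep])
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d cells x %d frames (+ background)\n",
              length(x$cells), x$n_frames))
  invisible(x)
}

#' Read and write the ROI JSON dialect
#'
#' The canonical on-disk form of a [roi_set()]: a JSON object with fields
#' `n_frames`, `background` (per-frame vertex lists) and `cells` (per cell
#' id, per frame, named `stripe` / `nucleus` vertex lists). Vertices are
#' `[x, y]` pairs in 0-based pixel units.
#'
#' @param rois a `roi_set`.
#' @param path file path.
#' @return `read_roi_json()` returns a `roi_set`; `write_roi_json()`
#'   returns `path` invisibly.
#' @export
write_roi_json <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  obj <- list(
    n_frames = rois$n_frames,
    background = lapply(rois$background, function(p) unname(as.matrix(p))),
    cells = lapply(rois$cells, function(cf)
      lapply(cf, function(fr) list(stripe = unname(as.matrix(fr$stripe)),
                                   nucleus = unname(as.matrix(fr$nucleus)))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_poly <- function(v) do.call(rbind, lapply(v, function(p) unlist(p)))
  roi_set(
    cells = lapply(obj$cells, function(cf)
      lapply(cf, function(fr) list(stripe = as_poly(fr$stripe),
                                   nucleus = as_poly(fr$nucleus)))),
    background = lapply(obj$background, as_poly)
  )
}

#' Import an ImageJ ROI file as a polygon
#'
#' Reads a single ImageJ `.roi` file (polygon, freehand, traced, rectangle
#' or oval types) and returns its outline as an n x 2 vertex matrix in this
#' package's 0-based pixel coordinates. `read_imagej_roi_zip()` reads every
#' `.roi` inside an ImageJ RoiSet `.zip`. The JSON dialect
#' ([write_roi_json()]) remains the canonical format; this importer only
#' recovers outlines, not the stripe/nucleus/background role of each ROI.
#'
#' @param path path to a `.roi` (or `.zip`) file.
#' @return an n x 2 polygon matrix (for the zip reader, a named list of
#'   them).
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:4]) != "Iout") stopf("not an ImageJ ROI file")
  be16 <- function(off) {  # big-endian signed int16 at 0-based offset
    v <- as.integer(raw[off + 1:2])
    x <- v[1] * 256L + v[2]
    if (x >= 32768L) x - 65536L else x
  }
  type <- as.integer(raw[7])
  top <- be16(8); left <- be16(10); bottom <- be16(12); right <- be16(14)
  n_coord <- be16(16)
  if (type %in% c(0L, 3L, 4L, 7L, 8L) && n_coord > 0L) {  # polygon-like
    xs <- vapply(seq_len(n_coord), function(i) be16(64 + 2 * (i - 1)), 0L)
    ys <- vapply(seq_len(n_coord), function(i) be16(64 + 2 * (n_coord + i - 1)), 0L)
    cbind(x = left + xs, y = top + ys)
  } else if (type == 1L) {        # rectangle
    rect_polygon(left, top, right - 1, bottom - 1)
  } else if (type == 2L) {        # oval
    ellipse_polygon((left + right - 1) / 2, (top + bottom - 1) / 2,
                    (right - left) / 2, (bottom - top) / 2)
  } else stopf("unsupported ImageJ ROI type %d", type)
}

#' @rdname read_imagej_roi
#' @export
read_imagej_roi_zip <- function(path) {
  dir <- tempfile("ijroi"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  files <- utils::unzip(path, exdir = dir)
  files <- files[grepl("\\.roi$", files)]
  out <- lapply(files, read_imagej_roi)
  names(out) <- sub("\\.roi$", "", basename(files))
  out
}
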