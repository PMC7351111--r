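# Polygon utilities. Polygons are n x 2 matrices of (x, y) vertices in
# pixel units, 0-based, pixel centers at integer coordinates. Rasterization
# rule: a pixel belongs to a polygon iff its center is strictly inside
# (even-odd rule) or on the boundary.

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || any(!is.finite(p)))
    stopf("a polygon is an n x 2 (x, y) matrix with n >= 3 finite vertices")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel (center at integer 0-based coordinates) is in the mask iff its
#' center is strictly inside the polygon by the even-odd rule, or lies on
#' the polygon boundary.
#'
#' @param poly n x 2 matrix of (x, y) vertices in pixel units.
#' @param dim image dimension `c(height, width)`.
#' @return logical matrix of dimension `dim`, indexed `[y + 1, x + 1]`.
#' @export
polygon_mask <- function(poly, dim) {
  poly <- as_polygon(poly)
  h <- as.integer(dim[1]); w <- as.integer(dim[2])
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- max(0L, ceiling(xr[1] - 1e-9)):min(w - 1L, floor(xr[2] + 1e-9))
  ys <- max(0L, ceiling(yr[1] - 1e-9)):min(h - 1L, floor(yr[2] + 1e-9))
  mask <- matrix(FALSE, h, w)
  if (xr[1] > w - 1 || xr[2] < 0 || yr[1] > h - 1 || yr[2] < 0) return(mask)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- points_in_polygon(px, py, poly)
  mask[cbind(py + 1L, px + 1L)] <- inside
  mask
}

# Vectorized even-odd point-in-polygon with boundary inclusion.
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  cross <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    # on-segment test: zero cross product and within the segment bbox
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    onseg <- abs(d) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | onseg
    # even-odd ray casting (ray towards +x), half-open in y to avoid
    # double-counting vertices
    hit <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    hit[is.na(hit)] <- FALSE
    cross <- xor(cross, hit)
  }
  cross | onedge
}

#' Translate a polygon
#'
#' @param poly n x 2 vertex matrix.
#' @param dx,dy shift in pixels.
#' @return the shifted polygon.
#' @export
translate_polygon <- function(poly, dx, dy) {
  poly <- as_polygon(poly)
  poly[, 1] <- poly[, 1] + dx
  poly[, 2] <- poly[, 2] + dy
  poly
}

# Area-weighted centroid of a simple polygon (shoelace); falls back to the
# vertex mean for degenerate (zero-area) input.
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Axis-aligned rectangle polygon from corner (x0, y0) to (x1, y1).
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Closed ellipse polygon approximation.
ellipse_polygon <- function(cx, cy, a, b, n = 64L, theta0 = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] + theta0
  cbind(x = cx + a * cos(th), y = cy + b * sin(th))
}
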