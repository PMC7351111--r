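# Independent brute-force oracles. These deliberately re-derive results
# with different algorithms than the package (angle-summation winding
# test vs ray casting; scalar double loops vs vectorized masks).

# Scalar point-in-polygon by angle summation, boundary included.
oracle_point_in_poly <- function(x, y, poly, eps = 1e-9) {
  n <- nrow(poly)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1] - x; ay <- poly[i, 2] - y
    bx <- poly[j, 1] - x; by <- poly[j, 2] - y
    # boundary: point-to-segment distance
    vx <- poly[j, 1] - poly[i, 1]; vy <- poly[j, 2] - poly[i, 2]
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((x - poly[i, 1]) * vx +
                                              (y - poly[i, 2]) * vy) / L2))
    dx <- x - (poly[i, 1] + t * vx); dy <- y - (poly[i, 2] + t * vy)
    if (dx^2 + dy^2 <= eps^2) return(TRUE)
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(total) > pi  # winding number != 0 (even-odd equivalent for simple polygons)
}

# Mean intensity over pixel centers inside a polygon, full double loop.
oracle_poly_mean <- function(img, poly) {
  s <- 0; n <- 0L
  for (yy in 0:(nrow(img) - 1L)) {
    for (xx in 0:(ncol(img) - 1L)) {
      if (oracle_point_in_poly(xx, yy, poly)) {
        s <- s + img[yy + 1L, xx + 1L]
        n <- n + 1L
      }
    }
  }
  if (n == 0L) NA_real_ else s / n
}

# Row-loop version of the foci-burden statistic.
oracle_foci_fraction <- function(table, threshold) {
  if (is.null(table$condition)) table$condition <- "all"
  out <- list()
  for (cond in unique(table$condition)) {
    for (tp in sort(unique(table$timepoint_h[table$condition == cond]))) {
      pcts <- c()
      sub1 <- table[table$condition == cond & table$timepoint_h == tp, ]
      for (e in unique(sub1$experiment)) {
        g <- sub1[sub1$experiment == e, ]
        hits <- 0L
        for (k in seq_len(nrow(g))) if (g$count[k] > threshold) hits <- hits + 1L
        pcts <- c(pcts, 100 * hits / nrow(g))
      }
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, timepoint_h = tp, mean_pct = mean(pcts),
        sem_pct = if (length(pcts) > 1) stats::sd(pcts) / sqrt(length(pcts))
                  else NA_real_,
        n_experiments = length(pcts))
    }
  }
  do.call(rbind, out)
}

# Random simple polygon fully inside an h x w image: triangle, rectangle
# or convex blob around a center point.
random_polygon <- function(h, w) {
  kind <- sample(c("tri", "rect", "blob"), 1)
  if (kind == "rect") {
    x0 <- runif(1, 0, w - 3); y0 <- runif(1, 0, h - 3)
    x1 <- runif(1, x0 + 1.5, w - 1); y1 <- runif(1, y0 + 1.5, h - 1)
    return(cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
  }
  if (kind == "tri") {
    repeat {
      p <- cbind(x = runif(3, 0, w - 1), y = runif(3, 0, h - 1))
      # ensure it covers at least one pixel center and is not degenerate
      a <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                 (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
      if (a > 4) return(p)
    }
  }
  r <- runif(1, 1.5, max(1.6, min(h, w) / 4))
  cx <- runif(1, r + 0.2, w - 1 - r - 0.2)
  cy <- runif(1, r + 0.2, h - 1 - r - 0.2)
  th <- sort(runif(sample(5:9, 1), 0, 2 * pi))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Small measurement table with a known pre-irradiation mean.
make_curves <- function(sx_mat, t_s) {
  # sx_mat: cells x timepoints
  do.call(rbind, lapply(seq_len(nrow(sx_mat)), function(i) {
    data.frame(cell_id = sprintf("c%02d", i), frame = seq_along(t_s),
               t_s = t_s, sx = sx_mat[i, ])
  }))
}
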