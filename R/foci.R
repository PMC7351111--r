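#' Detect nuclear foci in a z-stack
#'
#' Maximum-intensity projection over z followed by single-scale
#' Laplacian-of-Gaussian blob detection inside each nucleus mask: local
#' maxima of the (sign-flipped, scale-normalized) LoG response whose
#' projected intensity exceeds `rel_thresh` times the median intensity of
#' their nucleus, with greedy minimum-separation suppression (strongest
#' response wins). The threshold is relative, so counts are invariant to a
#' global gain change. A stack without a z dimension is treated as a
#' single plane with a warning.
#'
#' @param stack an [image_stack()] with z planes (`z = TRUE`).
#' @param masks integer label matrix (0 = outside, 1..n = nucleus id) of
#'   the same 2D dimension as the frames.
#' @param psf_sigma LoG scale (expected spot sigma), pixels.
#' @param rel_thresh intensity threshold relative to the nuclear median of
#'   the projection.
#' @param min_sep minimum distance between accepted peaks, pixels.
#' @return data.frame with columns `cell_id` (`"cell001"`, ... matching
#'   mask labels), `count`.
#' @export
detect_foci <- function(stack, masks, psf_sigma = 1.5, rel_thresh = 1.3,
                        min_sep = 4) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack$z) {
    warnf("stack has no z dimension; treating it as a single plane")
  }
  mip <- max_project(stack)
  if (!identical(dim(mip), dim(masks)))
    stopf("mask dimension does not match the stack frames")
  n_nuc <- max(masks)
  if (n_nuc < 1L || !any(masks > 0L)) stopf("empty mask")

  # scale-normalized LoG, sign flipped so bright blobs give positive peaks
  sg <- psf_sigma
  r <- ceiling(3 * sg)
  ax <- -r:r
  g2 <- outer(ax^2, ax^2, "+")
  log_k <- -(g2 - 2 * sg^2) / sg^2 * exp(-g2 / (2 * sg^2))
  resp <- conv2_same(mip, log_k)

  # 8-neighborhood local maxima
  h <- nrow(resp); w <- ncol(resp)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- resp
  nb_max <- matrix(-Inf, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, pad[2:(h + 1) + dy, 2:(w + 1) + dx])
  }
  is_peak <- resp >= nb_max & resp > 0

  # brightness at a peak: 3x3 neighborhood max of the projection (the LoG
  # peak can sit one pixel off the intensity peak under noise)
  padm <- matrix(-Inf, h + 2, w + 2)
  padm[2:(h + 1), 2:(w + 1)] <- mip
  mip_nb <- mip
  for (dy in -1:1) for (dx in -1:1) {
    mip_nb <- pmax(mip_nb, padm[2:(h + 1) + dy, 2:(w + 1) + dx])
  }

  counts <- integer(n_nuc)
  for (i in seq_len(n_nuc)) {
    inside <- masks == i
    if (!any(inside)) stopf("empty mask for nucleus %d", i)
    med <- stats::median(mip[inside])
    idx <- which(is_peak & inside & mip_nb > rel_thresh * med)
    if (length(idx) == 0L) { counts[i] <- 0L; next }
    py <- (idx - 1L) %% h
    px <- (idx - 1L) %/% h
    ord <- order(resp[idx], decreasing = TRUE)
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (j in ord) {
      if (length(keep_x) == 0L ||
          min((keep_x - px[j])^2 + (keep_y - py[j])^2) >= min_sep^2) {
        keep_x <- c(keep_x, px[j]); keep_y <- c(keep_y, py[j])
      }
    }
    counts[i] <- length(keep_x)
  }
  data.frame(cell_id = sprintf("cell%03d", seq_len(n_nuc)), count = counts,
             stringsAsFactors = FALSE)
}

#' Fraction of cells exceeding a foci-count threshold
#'
#' The foci-burden statistic: per experiment, condition and timepoint, the
#' percentage of cells with strictly more than `threshold` foci per
#' nucleus (cells at exactly the threshold are excluded), then the mean
#' and SEM of those percentages across independent experiments.
#'
#' @param table data.frame with columns `experiment`, `timepoint_h`,
#'   `cell_id`, `count`, and optionally `condition`.
#' @param threshold integer count threshold (strict `>`); 10 by default.
#' @return a data.frame of class `foci_summary` with columns `condition`,
#'   `timepoint_h`, `mean_pct`, `sem_pct`, `n_experiments`, and the
#'   per-experiment percentages in the `per_experiment` attribute.
#' @export
foci_fraction <- function(table, threshold = 10L) {
  stopifnot(all(c("experiment", "timepoint_h", "cell_id", "count") %in%
                  names(table)),
            threshold >= 0, threshold == round(threshold))
  if (any(table$count < 0)) stopf("foci counts must be >= 0")
  if (is.null(table$condition)) table$condition <- "all"
  key <- interaction(table$condition, table$timepoint_h, table$experiment,
                     drop = TRUE)
  per_exp <- do.call(rbind, lapply(split(table, key), function(g) {
    data.frame(condition = g$condition[1], timepoint_h = g$timepoint_h[1],
               experiment = g$experiment[1],
               pct = 100 * mean(g$count > threshold),
               n_cells = nrow(g), stringsAsFactors = FALSE)
  }))
  row.names(per_exp) <- NULL
  key2 <- interaction(per_exp$condition, per_exp$timepoint_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_exp, key2), function(g) {
    data.frame(condition = g$condition[1], timepoint_h = g$timepoint_h[1],
               mean_pct = mean(g$pct),
               sem_pct = if (nrow(g) > 1) sem(g$pct) else NA_real_,
               n_experiments = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$timepoint_h), ]
  row.names(out) <- NULL
  structure(out, per_experiment = per_exp, threshold = as.integer(threshold),
            class = c("foci_summary", "data.frame"))
}

#' Compare foci burden between two conditions
#'
#' Two-sample two-tailed Student's t test on the per-experiment
#' percentages at each shared timepoint, significant at p < 0.05.
#'
#' @param summary_a,summary_b [foci_fraction()] results (one condition
#'   each).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data.frame with columns `timepoint_h`, `mean_a`, `mean_b`, `p`,
#'   `significant`.
#' @export
compare_foci <- function(summary_a, summary_b, var_equal = TRUE) {
  pa <- attr(summary_a, "per_experiment")
  pb <- attr(summary_b, "per_experiment")
  stopifnot(!is.null(pa), !is.null(pb))
  tps <- intersect(unique(pa$timepoint_h), unique(pb$timepoint_h))
  if (length(tps) == 0L) stopf("no shared timepoints")
  out <- lapply(sort(tps), function(t) {
    xa <- pa$pct[pa$timepoint_h == t]
    xb <- pb$pct[pb$timepoint_h == t]
    if (length(xa) < 2L || length(xb) < 2L)
      stopf("need >= 2 experiments per condition at each timepoint")
    p <- student_t_p(xa, xb, var_equal = var_equal)
    data.frame(timepoint_h = t, mean_a = mean(xa), mean_b = mean(xb),
               p = p, significant = p < 0.05)
  })
  do.call(rbind, out)
}
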