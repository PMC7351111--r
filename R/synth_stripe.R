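#' Configuration for the synthetic stripe-recruitment movie
#'
#' Describes a simulated laser-microirradiation acquisition: a field of
#' elliptical nuclei, each crossed by a narrow horizontal stripe whose
#' relative brightness follows a lagged saturating-exponential recruitment
#' law with optional late exponential decay (emulating slow diffusion of
#' the recruited protein out of the initially narrow stripe),
#'
#' \deqn{S(t) = 1 + A (1 - e^{-k (t - t_{lag})}) e^{-d \max(0, t - t_{lag})}}
#'
#' for \eqn{t \ge t_{lag}} and 1 before. Irradiation happens at t = 0; the
#' first frame is the pre-irradiation acquisition and must have t < 0.
#' Whole frames are photobleached multiplicatively by `exp(-bleach_rate *
#' (t - t[1]))`, optionally drifted at a constant per-cell velocity, and
#' corrupted by Poisson shot noise plus Gaussian read noise.
#'
#' @param image_dim image size `c(height, width)` in pixels.
#' @param n_cells number of nuclei in the field.
#' @param nucleus_axes ellipse semi-axes `c(a, b)` in pixels (x, y).
#' @param jitter per-cell center jitter, pixels (uniform in +/- jitter).
#' @param stripe_width full stripe width in pixels.
#' @param stripe_frac stripe length as a fraction of the nucleus x-extent.
#' @param timestamps frame times in seconds, strictly increasing; the first
#'   must be negative (pre-irradiation).
#' @param a_true plateau amplitude A (dimensionless stripe/nucleus contrast).
#' @param k_true recruitment rate k, 1/s.
#' @param t_lag lag before recruitment starts, s (>= 0).
#' @param d_true late decay rate d, 1/s (0 disables the decay).
#' @param i_nuc,i_bg baseline nuclear / background intensity (arbitrary
#'   camera units, `i_nuc > i_bg >= 0`).
#' @param bleach_rate photobleaching rate beta, 1/s.
#' @param drift per-frame drift velocity `c(vx, vy)` in pixels/frame,
#'   applied to every cell (direction randomized per cell when
#'   `drift_random_dir = TRUE`).
#' @param drift_random_dir randomize the drift direction per cell, keeping
#'   the stated speed.
#' @param poisson_noise apply Poisson shot noise.
#' @param read_sd Gaussian read-noise standard deviation (camera units).
#' @param seed master RNG seed; all per-cell and per-frame substreams are
#'   derived from it deterministically.
#' @return a validated list of class `stripe_sim_config`.
#' @export
stripe_sim_config <- function(image_dim = c(256L, 256L),
                              n_cells = 10L,
                              nucleus_axes = c(16, 11),
                              jitter = 2,
                              stripe_width = 5,
                              stripe_frac = 0.6,
                              timestamps = c(-5, seq(30, 300, by = 30)),
                              a_true = 1.0,
                              k_true = 0.02,
                              t_lag = 0,
                              d_true = 0,
                              i_nuc = 400,
                              i_bg = 60,
                              bleach_rate = 5e-4,
                              drift = c(0, 0),
                              drift_random_dir = FALSE,
                              poisson_noise = TRUE,
                              read_sd = 3,
                              seed = 1L) {
  cfg <- list(image_dim = as.integer(image_dim), n_cells = as.integer(n_cells),
              nucleus_axes = nucleus_axes, jitter = jitter,
              stripe_width = stripe_width, stripe_frac = stripe_frac,
              timestamps = as.numeric(timestamps), a_true = a_true,
              k_true = k_true, t_lag = t_lag, d_true = d_true,
              i_nuc = i_nuc, i_bg = i_bg, bleach_rate = bleach_rate,
              drift = as.numeric(drift), drift_random_dir = isTRUE(drift_random_dir),
              poisson_noise = isTRUE(poisson_noise), read_sd = read_sd,
              seed = as.integer(seed))
  class(cfg) <- "stripe_sim_config"
  validate_stripe_sim_config(cfg)
}

validate_stripe_sim_config <- function(cfg) {
  with(cfg, {
    if (length(timestamps) < 2L || any(diff(timestamps) <= 0))
      stopf("timestamps must be strictly increasing with >= 2 frames")
    if (timestamps[1] >= 0)
      stopf("the first frame is pre-irradiation and must have t < 0")
    if (!(i_nuc > i_bg && i_bg >= 0)) stopf("need i_nuc > i_bg >= 0")
    if (a_true < 0 || k_true < 0 || t_lag < 0 || d_true < 0 || bleach_rate < 0)
      stopf("amplitudes and rates must be >= 0")
    if (read_sd < 0) stopf("read_sd must be >= 0")
    # stripe rectangle corners must sit inside the smallest jittered nucleus
    a_min <- nucleus_axes[1] * 0.9
    b_min <- nucleus_axes[2] * 0.9
    hx <- stripe_frac * nucleus_axes[1]
    hy <- stripe_width / 2
    if ((hx / a_min)^2 + (hy / b_min)^2 > 1)
      stopf("stripe outside nucleus")
    if (b_min - hy < 3.5)
      stopf("nucleus-remainder lobe too thin; reduce stripe_width or enlarge nucleus")
  })
  cfg
}

#' True recruitment law
#'
#' Relative stripe brightness over time under the simulator's lagged
#' saturating-exponential law with optional exponential decay. Equals 1 for
#' all t below the lag (and at any pre-irradiation time).
#'
#' @param t time in seconds (irradiation at t = 0).
#' @param a plateau amplitude A.
#' @param k recruitment rate, 1/s.
#' @param t_lag lag, s.
#' @param d late decay rate, 1/s.
#' @return numeric vector of S(t) values.
#' @examples
#' s_true(60, a = 1, k = 0.02)  # 1 + (1 - exp(-1.2))
#' @export
s_true <- function(t, a, k, t_lag = 0, d = 0) {
  dt <- t - t_lag
  ifelse(t >= t_lag & dt >= 0,
         1 + a * (1 - exp(-k * dt)) * exp(-d * pmax(0, dt)),
         1)
}

#' Simulate a stripe-recruitment movie with ground truth
#'
#' Renders each frame as
#' `i_bg + (i_nuc - i_bg) * M_nuc * (1 + (S(t) - 1) * M_stripe)`,
#' multiplies by the bleaching factor, applies per-cell drift to the
#' geometry, then adds Poisson shot noise and Gaussian read noise. The
#' returned ROI set follows the drifted geometry exactly (as a careful
#' manual annotator would), and the ground truth carries the noiseless
#' region means and the true S(t) series.
#'
#' @param config a [stripe_sim_config()].
#' @return a list with elements `stack` ([image_stack()]), `rois`
#'   ([roi_set()]) and `truth` (list with `s_true`, per-cell/frame
#'   `true_means` data.frame, and the per-cell drift velocities).
#' @export
simulate_stripe_movie <- function(config) {
  cfg <- validate_stripe_sim_config(config)
  h <- cfg$image_dim[1]; w <- cfg$image_dim[2]
  n <- cfg$n_cells
  ts <- cfg$timestamps
  nf <- length(ts)
  st <- s_true(ts, cfg$a_true, cfg$k_true, cfg$t_lag, cfg$d_true)
  bleach <- exp(-cfg$bleach_rate * (ts - ts[1]))

  # --- geometry: jittered grid of nuclei, left margin reserved for the
  # background ROI ---
  margin_x <- 26
  nc <- max(1L, ceiling(sqrt(n * (w - margin_x) / h)))
  nr <- ceiling(n / nc)
  bw <- (w - margin_x) / nc; bh <- h / nr
  max_shift <- max(abs(cfg$drift)) * (nf - 1)
  need <- max(cfg$nucleus_axes) * 1.1 + cfg$jitter + max_shift + 2
  if (bw / 2 < need || bh / 2 < need)
    stopf("%d cells do not fit a %dx%d field with the given geometry/drift",
          n, w, h)

  geom <- with_seed(subseed(cfg$seed, 0L), {
    lapply(seq_len(n), function(i) {
      r <- (i - 1) %/% nc; cl <- (i - 1) %% nc
      cx <- margin_x + (cl + 0.5) * bw + stats::runif(1, -cfg$jitter, cfg$jitter)
      cy <- (r + 0.5) * bh + stats::runif(1, -cfg$jitter, cfg$jitter)
      ax <- cfg$nucleus_axes[1] * stats::runif(1, 0.9, 1.1)
      bx <- cfg$nucleus_axes[2] * stats::runif(1, 0.9, 1.1)
      v <- if (cfg$drift_random_dir && any(cfg$drift != 0)) {
        ang <- stats::runif(1, 0, 2 * pi)
        sqrt(sum(cfg$drift^2)) * c(cos(ang), sin(ang))
      } else cfg$drift
      list(cx = cx, cy = cy, a = ax, b = bx, v = v)
    })
  })

  bg_poly <- rect_polygon(3, 3, margin_x - 6, 21)
  cell_polys <- function(g, shift) {
    cx <- g$cx + shift[1]; cy <- g$cy + shift[2]
    hx <- cfg$stripe_frac * g$a; hy <- cfg$stripe_width / 2
    gap <- 1.5
    alpha <- asin(pmin(1, (hy + gap) / g$b))
    th <- seq(pi + alpha, 2 * pi - alpha, length.out = 24L)
    lobe <- cbind(x = cx + g$a * cos(th), y = cy + g$b * sin(th))
    list(nucleus_full = ellipse_polygon(cx, cy, g$a, g$b),
         stripe = rect_polygon(cx - hx, cy - hy, cx + hx, cy + hy),
         lobe = lobe)
  }

  frames <- vector("list", nf)
  cells_rois <- stats::setNames(
    lapply(seq_len(n), function(i) vector("list", nf)),
    sprintf("cell%02d", seq_len(n)))
  true_means <- vector("list", nf * n)
  masks_cache <- NULL; cache_key <- NULL

  for (f in seq_len(nf)) {
    shifts <- lapply(geom, function(g) g$v * (f - 1))
    key <- paste(unlist(shifts), collapse = ",")
    if (is.null(cache_key) || key != cache_key) {
      masks_cache <- lapply(seq_len(n), function(i) {
        p <- cell_polys(geom[[i]], shifts[[i]])
        mn <- polygon_mask(p$nucleus_full, c(h, w))
        ms <- polygon_mask(p$stripe, c(h, w)) & mn
        list(polys = p, mn = mn, ms = ms)
      })
      cache_key <- key
    }
    img <- matrix(cfg$i_bg, h, w)
    for (i in seq_len(n)) {
      mc <- masks_cache[[i]]
      img[mc$mn] <- cfg$i_bg + (cfg$i_nuc - cfg$i_bg)
      img[mc$ms] <- cfg$i_bg + (cfg$i_nuc - cfg$i_bg) * st[f]
      cells_rois[[i]][[f]] <- list(stripe = mc$polys$stripe,
                                   nucleus = mc$polys$lobe)
      true_means[[(f - 1) * n + i]] <- data.frame(
        cell_id = names(cells_rois)[i], frame = f, t_s = ts[f],
        stripe_mean = bleach[f] * (cfg$i_bg + (cfg$i_nuc - cfg$i_bg) * st[f]),
        nucleus_mean = bleach[f] * cfg$i_nuc,
        bg_mean = bleach[f] * cfg$i_bg,
        s_true = st[f], stringsAsFactors = FALSE)
    }
    img <- img * bleach[f]
    img <- with_seed(subseed(cfg$seed, 1L, f), {
      noisy <- if (cfg$poisson_noise)
        matrix(stats::rpois(length(img), img), h, w) else img
      if (cfg$read_sd > 0)
        noisy <- noisy + matrix(stats::rnorm(length(img), 0, cfg$read_sd), h, w)
      noisy
    })
    frames[[f]] <- pmax(img, 0)
  }

  list(stack = image_stack(frames, ts),
       rois = roi_set(cells = cells_rois, background = rep(list(bg_poly), nf),
                      validate = FALSE),
       truth = list(s_true = st,
                    true_means = do.call(rbind, true_means),
                    drift = lapply(geom, `[[`, "v"),
                    config = cfg))
}
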