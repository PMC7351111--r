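#' Simulate nuclear-foci z-stacks with known counts
#'
#' Emulates a foci time-course acquisition: at each timepoint a field of
#' disk-shaped nuclei is imaged as a z-stack; each nucleus carries a
#' Poisson-distributed number of foci whose mean grows linearly with time,
#' `mean(t) = foci_mean_t0 + foci_rate_per_hour * t`. Each focus is
#' rendered as a 3D Gaussian spot at a random position inside its nucleus
#' (rejection-sampled to honor a minimum in-plane separation; if that
#' fails after many tries the spot is placed anyway with a warning — the
#' returned counts stay truthful). Planes receive Poisson shot noise plus
#' Gaussian read noise.
#'
#' @param n_cells nuclei per field.
#' @param foci_rate_per_hour growth of the mean foci count, 1/h.
#' @param foci_mean_t0 mean foci count at t = 0 h.
#' @param timepoints_h acquisition timepoints in hours.
#' @param z_planes number of z planes per field.
#' @param psf_sigma spot Gaussian sigmas `c(xy, z)` in pixels / planes.
#' @param nucleus_radius nucleus disk radius, pixels.
#' @param spot_amp peak spot amplitude above the nuclear baseline (camera
#'   units).
#' @param i_nuc,i_bg nuclear / background baseline intensity.
#' @param read_sd Gaussian read-noise sd; `poisson_noise` toggles shot
#'   noise.
#' @param poisson_noise apply Poisson shot noise.
#' @param min_sep minimum in-plane distance between spot centers, pixels.
#' @param seed master RNG seed.
#' @return list with `stacks` (per timepoint, an [image_stack()] with
#'   `z = TRUE`), `masks` (per timepoint, an integer nucleus label
#'   matrix), and `truth` (data.frame `timepoint_h`, `cell_id`, `count`).
#' @export
simulate_foci_stack <- function(n_cells = 20L,
                                foci_rate_per_hour = 2.5,
                                foci_mean_t0 = 2,
                                timepoints_h = c(0, 2, 4),
                                z_planes = 21L,
                                psf_sigma = c(1.5, 2),
                                nucleus_radius = 16,
                                spot_amp = 150,
                                i_nuc = 200, i_bg = 40,
                                read_sd = 3,
                                poisson_noise = TRUE,
                                min_sep = 5,
                                seed = 1L) {
  stopifnot(z_planes >= 1L, n_cells >= 1L, foci_rate_per_hour >= 0,
            foci_mean_t0 >= 0, i_nuc > i_bg, i_bg >= 0)
  # grid layout of nuclei
  nc <- ceiling(sqrt(n_cells))
  nr <- ceiling(n_cells / nc)
  cell_box <- 2 * nucleus_radius + 8
  h <- nr * cell_box; w <- nc * cell_box
  centers <- lapply(seq_len(n_cells), function(i) {
    r <- (i - 1) %/% nc; cl <- (i - 1) %% nc
    c((cl + 0.5) * cell_box, (r + 0.5) * cell_box)
  })
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  labels <- matrix(0L, h, w)
  for (i in seq_len(n_cells)) {
    d2 <- (xg - centers[[i]][1])^2 + (yg - centers[[i]][2])^2
    labels[d2 <= nucleus_radius^2] <- i
  }

  sxy <- psf_sigma[1]; sz <- if (length(psf_sigma) > 1) psf_sigma[2] else 2
  rad <- ceiling(3 * sxy)
  stacks <- list(); masks <- list(); truth <- list(); positions_all <- list()

  for (ti in seq_along(timepoints_h)) {
    t_h <- timepoints_h[ti]
    lam <- foci_mean_t0 + foci_rate_per_hour * t_h
    res <- with_seed(subseed(seed, ti), {
      counts <- stats::rpois(n_cells, lam)
      base <- matrix(i_bg, h, w)
      base[labels > 0L] <- i_nuc
      planes <- lapply(seq_len(z_planes), function(z) base)
      positions <- list()
      for (i in seq_len(n_cells)) {
        pos <- matrix(0, 0, 3)
        for (s in seq_len(counts[i])) {
          ok <- FALSE
          for (try in 1:100) {
            rr <- sqrt(stats::runif(1)) * (nucleus_radius - 3)
            th <- stats::runif(1, 0, 2 * pi)
            cand <- c(centers[[i]][1] + rr * cos(th),
                      centers[[i]][2] + rr * sin(th),
                      stats::runif(1, z_planes * 0.3, z_planes * 0.7))
            if (nrow(pos) == 0 ||
                min((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) >= min_sep^2) {
              ok <- TRUE; break
            }
          }
          if (!ok)
            warnf("could not honor min_sep = %g for nucleus %d; spot placed anyway",
                  min_sep, i)
          pos <- rbind(pos, cand)
        }
        positions[[i]] <- pos
        if (nrow(pos) > 0) for (s in seq_len(nrow(pos))) {
          x0 <- pos[s, 1]; y0 <- pos[s, 2]; z0 <- pos[s, 3]
          xs <- max(0, floor(x0 - rad)):min(w - 1, ceiling(x0 + rad))
          ys <- max(0, floor(y0 - rad)):min(h - 1, ceiling(y0 + rad))
          gx <- exp(-((xs - x0)^2) / (2 * sxy^2))
          gy <- exp(-((ys - y0)^2) / (2 * sxy^2))
          patch <- outer(gy, gx)
          for (z in seq_len(z_planes)) {
            az <- spot_amp * exp(-((z - z0)^2) / (2 * sz^2))
            if (az < 1e-3) next
            planes[[z]][ys + 1L, xs + 1L] <-
              planes[[z]][ys + 1L, xs + 1L] + az * patch
          }
        }
      }
      planes <- lapply(planes, function(p) {
        q <- if (poisson_noise) matrix(stats::rpois(length(p), p), h, w) else p
        if (read_sd > 0) q <- q + matrix(stats::rnorm(length(p), 0, read_sd), h, w)
        pmax(q, 0)
      })
      list(planes = planes, counts = counts, positions = positions)
    })
    stacks[[ti]] <- image_stack(res$planes, seq_len(z_planes), z = TRUE)
    positions_all[[ti]] <- res$positions
    masks[[ti]] <- labels
    truth[[ti]] <- data.frame(timepoint_h = t_h,
                              cell_id = sprintf("cell%03d", seq_len(n_cells)),
                              count = res$counts, stringsAsFactors = FALSE)
  }
  list(stacks = stacks, masks = masks, truth = do.call(rbind, truth),
       positions = positions_all)
}
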