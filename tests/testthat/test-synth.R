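small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 3, image_dim = c(96L, 200L),
         timestamps = c(-5, 30, 60, 120)),
    list(...))
  do.call(stripe_sim_config, args)
}

test_that("the recruitment law matches its closed form", {
  # no recruitment before irradiation, saturating rise after
  expect_identical(s_true(-5, a = 1, k = 0.02), 1)
  expect_equal(s_true(60, a = 1, k = 0.02), 1 + (1 - exp(-1.2)))
  expect_equal(s_true(60, a = 1, k = 0.02), 1.6988, tolerance = 1e-4)
  # lag shifts the origin; decay multiplies in after the lag
  expect_identical(s_true(10, a = 1, k = 0.02, t_lag = 20), 1)
  expect_equal(s_true(80, a = 2, k = 0.05, t_lag = 20, d = 0.001),
               1 + 2 * (1 - exp(-0.05 * 60)) * exp(-0.001 * 60))
  # monotone non-decreasing when d = 0
  tt <- seq(0, 600, by = 5)
  expect_true(all(diff(s_true(tt, a = 1.3, k = 0.01)) >= 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulate_stripe_movie(small_cfg(seed = 11))
  s2 <- simulate_stripe_movie(small_cfg(seed = 11))
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$rois, s2$rois)
  s3 <- simulate_stripe_movie(small_cfg(seed = 12))
  expect_false(identical(s1$stack$frames, s3$stack$frames))
})

test_that("noiseless bleach-free rendering recovers S_true through the pipeline", {
  sim <- simulate_stripe_movie(small_cfg(poisson_noise = FALSE, read_sd = 0,
                                         bleach_rate = 0, seed = 3))
  cu <- sx_curves(measure_rois(sim$stack, sim$rois))
  for (cid in unique(cu$cell_id)) {
    expect_equal(cu$sx[cu$cell_id == cid], sim$truth$s_true, tolerance = 1e-9)
  }
  # a_true = 0: contrast ratio is exactly 1 at every frame, noise or not
  sim0 <- simulate_stripe_movie(small_cfg(a_true = 0, poisson_noise = FALSE,
                                          read_sd = 0, seed = 4))
  cu0 <- sx_curves(measure_rois(sim0$stack, sim0$rois))
  expect_equal(cu0$sx, rep(1, nrow(cu0)), tolerance = 1e-12)
})

test_that("photobleaching leaves the ratio statistic unchanged", {
  base <- small_cfg(poisson_noise = FALSE, read_sd = 0, bleach_rate = 0,
                    seed = 6)
  bleached <- small_cfg(poisson_noise = FALSE, read_sd = 0,
                        bleach_rate = 0.002, seed = 6)
  s_base <- sx_curves(measure_rois(
    simulate_stripe_movie(base)$stack, simulate_stripe_movie(base)$rois))
  sim_b <- simulate_stripe_movie(bleached)
  s_bl <- sx_curves(measure_rois(sim_b$stack, sim_b$rois))
  expect_equal(s_bl$sx, s_base$sx, tolerance = 1e-9)
  # the frames themselves do differ
  expect_gt(max(abs(simulate_stripe_movie(base)$stack$frames[[4]] -
                      sim_b$stack$frames[[4]])), 1)
})

test_that("drift displaces the ground-truth stripe centroid as stated", {
  cfg <- stripe_sim_config(n_cells = 1, image_dim = c(96L, 200L),
                           timestamps = c(-5, seq(10, 100, by = 10)),
                           drift = c(0.5, 0), poisson_noise = FALSE,
                           read_sd = 0, seed = 2)
  sim <- simulate_stripe_movie(cfg)
  c0 <- recruitkin:::polygon_centroid(sim$rois$cells[[1]][[1]]$stripe)
  c10 <- recruitkin:::polygon_centroid(sim$rois$cells[[1]][[11]]$stripe)
  expect_equal(c10 - c0, c(5, 0), tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(small_cfg(timestamps = c(5, 30, 60)), "pre-irradiation")
  expect_error(small_cfg(timestamps = c(-5, 60, 30)), "strictly increasing")
  expect_error(small_cfg(i_nuc = 50, i_bg = 60), "i_nuc > i_bg")
  expect_error(small_cfg(a_true = -1), ">= 0")
  expect_error(small_cfg(stripe_width = 30), "stripe outside nucleus")
})

test_that("foci simulator echoes geometry and count distribution", {
  fs <- simulate_foci_stack(n_cells = 4, timepoints_h = c(0, 2), z_planes = 21,
                            seed = 9)
  expect_length(fs$stacks, 2)
  expect_equal(dim_stack(fs$stacks[[1]])[3], 21)
  expect_true(fs$stacks[[1]]$z)
  # zero rate and zero baseline: all true counts 0
  fs0 <- simulate_foci_stack(n_cells = 6, foci_mean_t0 = 0,
                             foci_rate_per_hour = 0, timepoints_h = c(0, 4),
                             z_planes = 5, seed = 1)
  expect_true(all(fs0$truth$count == 0))
  # mean count at 4 h is within Poisson sampling error of 12 for 50 nuclei
  fs12 <- suppressWarnings(
    simulate_foci_stack(n_cells = 50, foci_mean_t0 = 2,
                        foci_rate_per_hour = 2.5, timepoints_h = 4,
                        z_planes = 3, seed = 21))
  # overdense request: the stated minimum separation cannot be honored,
  # which warns but keeps the returned counts truthful
  w <- testthat::capture_warnings(
    simulate_foci_stack(n_cells = 1, foci_mean_t0 = 40, timepoints_h = 0,
                        z_planes = 2, nucleus_radius = 10, seed = 1))
  expect_true(any(grepl("min_sep", w)))
  m <- mean(fs12$truth$count)
  expect_lt(abs(m - 12), 3 * sqrt(12 / 50))
  # determinism
  fsA <- simulate_foci_stack(n_cells = 3, z_planes = 4, seed = 5)
  fsB <- simulate_foci_stack(n_cells = 3, z_planes = 4, seed = 5)
  expect_identical(fsA$stacks[[1]]$frames, fsB$stacks[[1]]$frames)
  expect_identical(fsA$truth, fsB$truth)
})

test_that("survival simulator follows the stated binomial model", {
  # noise off: binomial expectation
  tab <- simulate_survival_counts(doses = c(0, 5), lambda = 0.1,
                                  plating_efficiency = 0.5,
                                  cells_plated = 1000, n_replicates = 1,
                                  stochastic = FALSE)
  expect_identical(tab$colonies[tab$dose == 0], 500L)
  expect_identical(tab$colonies[tab$dose == 5],
                   as.integer(round(1000 * 0.5 * exp(-0.5))))
  # identical seed twice: identical table
  t1 <- simulate_survival_counts(c(0, 2, 4), seed = 8)
  t2 <- simulate_survival_counts(c(0, 2, 4), seed = 8)
  expect_identical(t1, t2)
  # validation
  expect_error(simulate_survival_counts(c(0, 1), plating_efficiency = 0),
               "plating efficiency")
  expect_error(simulate_survival_counts(c(0, 1), cells_plated = 100),
               "cells_plated")
  expect_error(simulate_survival_counts(c(1, 2)), "0")
})
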