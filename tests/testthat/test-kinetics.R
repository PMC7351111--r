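test_that("compute_sx follows the ratio definition and its algebra", {
  expect_identical(compute_sx(1.5, 1.0, 0.5), 2)
  # stripe as bright as the nucleus: Sx = 1 whatever the background
  expect_identical(compute_sx(3.7, 3.7, 1.1), 1)
  # affine invariance: gain 3, offset 10 on all three measurements
  set.seed(31)
  ax <- runif(50, 100, 400); cx <- runif(50, 90, 300); b <- runif(50, 0, 80)
  keep <- cx > b
  expect_equal(compute_sx(3 * ax[keep] + 10, 3 * cx[keep] + 10, 3 * b[keep] + 10),
               compute_sx(ax[keep], cx[keep], b[keep]), tolerance = 1e-12)
  expect_error(compute_sx(1, 0.5, 0.5, cell_id = "c07", frame = 3),
               "degenerate contrast.*c07")
})

test_that("aggregation reproduces hand-computed mean and SEM", {
  cu <- make_curves(rbind(c(1.0, 1.5), c(3.0, 2.5)), t_s = c(-5, 30))
  agg <- aggregate_curves(cu)
  expect_equal(agg$mean_sx, c(2.0, 2.0))
  # sample sd of {1,3} is sqrt(2); SEM = sqrt(2)/sqrt(2) = 1
  expect_equal(agg$sem[1], 1.0)
  expect_identical(agg$n, c(2L, 2L))
  # identical cells: SEM 0 everywhere
  cu2 <- make_curves(rbind(c(1.2, 1.8), c(1.2, 1.8), c(1.2, 1.8)), c(-5, 30))
  expect_equal(aggregate_curves(cu2)$sem, c(0, 0))
  # errors: single cell, mismatched grids
  expect_error(aggregate_curves(make_curves(matrix(1, 1, 2), c(-5, 30))),
               ">= 2 cells")
  bad <- rbind(make_curves(matrix(1, 1, 2), c(-5, 30)),
               data.frame(cell_id = "c99", frame = 1:2, t_s = c(-5, 40),
                          sx = c(1, 1)))
  expect_error(aggregate_curves(bad), "common timepoint grid")
})

test_that("SEM scales as 1/sqrt(n) on repeated simulation", {
  set.seed(77)
  mean_sem <- vapply(c(4, 16, 64), function(n) {
    mean(replicate(300, sem(rnorm(n))))
  }, 0)
  ratios <- mean_sem[1] / mean_sem  # expected 1, 2, 4
  expect_equal(ratios, c(1, 2, 4), tolerance = 0.1)
})

test_that("additive normalization follows the stated rule", {
  # pre-irradiation mean 1.12: 0.12 subtracted everywhere
  cu <- make_curves(rbind(1.12 + c(0, 0.5, 0.9) - 0.02,
                          1.12 + c(0, 0.5, 0.9) + 0.02), c(-5, 60, 120))
  agg <- aggregate_curves(cu)
  expect_equal(agg$mean_sx[1], 1.12)
  nn <- normalize_to_t0(agg)
  expect_equal(attr(nn, "offset"), 0.12)
  expect_equal(nn$mean_sx, c(1, 1.5, 1.9))
  expect_identical(nn$sem, agg$sem)  # dispersion untouched
  # pre mean below 1: the difference is added
  cu2 <- make_curves(rbind(c(0.88, 1.3), c(0.92, 1.5)), c(-5, 60))
  n2 <- normalize_to_t0(aggregate_curves(cu2))
  expect_equal(attr(n2, "offset"), -0.1)
  expect_equal(n2$mean_sx, c(1, 1.5))
  # idempotence
  expect_equal(normalize_to_t0(nn), nn)
  # already-1 curve unchanged
  cu3 <- make_curves(rbind(c(0.9, 2), c(1.1, 2.2)), c(-5, 60))
  n3 <- normalize_to_t0(aggregate_curves(cu3))
  expect_equal(n3$mean_sx[1], 1)
})

test_that("condition comparison: Student t against stats::t.test", {
  set.seed(13)
  for (rep in 1:20) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, 0.8, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, 0.8, 2))
    expect_equal(recruitkin:::student_t_p(x, y),
                 stats::t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(recruitkin:::student_t_p(x, y, var_equal = FALSE),
                 stats::t.test(x, y)$p.value, tolerance = 1e-12)
  }
  # identical groups: p = 1, tier ns
  cuA <- make_curves(rbind(c(1, 2), c(1.2, 2.2)), c(-5, 60))
  cmp <- compare_conditions(cuA, cuA)
  expect_equal(cmp$p, c(1, 1))
  expect_equal(cmp$tier, c("ns", "ns"))
  # near-degenerate separation: tier ***
  set.seed(4)
  cuB <- make_curves(matrix(1 + rnorm(8, sd = 1e-6), 4, 2), c(-5, 60))
  cuC <- make_curves(matrix(2 + rnorm(8, sd = 1e-6), 4, 2), c(-5, 60))
  cmpBC <- compare_conditions(cuB, cuC)
  expect_true(all(cmpBC$p < 0.001))
  expect_true(all(cmpBC$tier == "***"))
  expect_error(compare_conditions(cuB, make_curves(matrix(1, 2, 2), c(0, 60))),
               "share a timepoint grid")
})

test_that("significance tiers map the printed thresholds", {
  expect_identical(significance_tier(c(0.9, 0.049, 0.0099, 0.00099)),
                   c("ns", "*", "**", "***"))
  expect_identical(significance_tier(c(0.05, 0.01, 0.001)),
                   c("ns", "*", "**"))  # boundaries are strict
})

test_that("affine intensity transforms leave the whole analysis unchanged", {
  sim <- simulate_stripe_movie(stripe_sim_config(
    n_cells = 4, image_dim = c(96L, 200L), timestamps = c(-5, 30, 60),
    seed = 17))
  g <- 2.5; cc <- 40
  scaled <- image_stack(lapply(sim$stack$frames, function(f) g * f + cc),
                        sim$stack$timestamps)
  cu1 <- sx_curves(measure_rois(sim$stack, sim$rois))
  cu2 <- sx_curves(measure_rois(scaled, sim$rois))
  expect_equal(cu2$sx, cu1$sx, tolerance = 1e-12)
  a1 <- normalize_to_t0(aggregate_curves(cu1))
  a2 <- normalize_to_t0(aggregate_curves(cu2))
  expect_equal(a2$mean_sx, a1$mean_sx, tolerance = 1e-12)
  expect_equal(a2$sem, a1$sem, tolerance = 1e-12)
})

test_that("plateau fitting recovers the simulated amplitude", {
  sim <- simulate_stripe_movie(stripe_sim_config(seed = 1))
  agg <- normalize_to_t0(aggregate_curves(sx_curves(
    measure_rois(sim$stack, sim$rois))))
  fit <- fit_plateau(agg)
  expect_equal(fit$a_hat, 1.0, tolerance = 0.1)
  expect_equal(fit$k_hat, 0.02, tolerance = 0.25)
})
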