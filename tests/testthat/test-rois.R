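test_that("measure_rois matches hand cases", {
  # uniform frame: every region mean is the constant
  st <- image_stack(list(matrix(7, 8, 8)), 0)
  rois <- roi_set(
    cells = list(c1 = list(list(stripe = rect_polygon(0.5, 0.5, 2.5, 1.5),
                                nucleus = rect_polygon(0.5, 4.5, 2.5, 6.5)))),
    background = list(rect_polygon(5, 5, 7, 7)))
  m <- measure_rois(st, rois)
  expect_equal(unlist(m[, c("Ax", "Cx", "B")]), c(Ax = 7, Cx = 7, B = 7))

  # 4x4 frame, left half 10, right half 20; stripe covering the left half
  img <- cbind(matrix(10, 4, 2), matrix(20, 4, 2))
  st2 <- image_stack(list(img), 0)
  stripe <- rect_polygon(-0.4, -0.4, 1.4, 3.4)  # pixel centers x in {0,1}
  rois2 <- roi_set(
    cells = list(c1 = list(list(stripe = stripe,
                                nucleus = rect_polygon(1.6, 0, 3.4, 3)))),
    background = list(rect_polygon(1.6, 0, 3.4, 3)))
  m2 <- measure_rois(st2, rois2)
  expect_identical(m2$Ax, 10)
  expect_identical(m2$Cx, 20)
})

test_that("measure_rois equals the double-loop pixel-mean oracle", {
  set.seed(101)
  for (rep in 1:40) {
    h <- sample(6:64, 1); w <- sample(6:64, 1)
    img <- matrix(runif(h * w, 0, 1000), h, w)
    poly <- random_polygon(h, w)
    expected <- oracle_poly_mean(img, poly)
    if (is.na(expected)) next  # polygon covered no pixel center
    st <- image_stack(list(img), 0)
    # random polygon measured as the (unconstrained) background ROI; the
    # stripe/nucleus pair is a fixed disjoint in-bounds placement
    rois <- roi_set(cells = list(c1 = list(list(
      stripe = rect_polygon(0, 0, 1.4, 1.4),
      nucleus = rect_polygon(3, 0, 4.4, 1.4)))),
      background = list(poly))
    m <- measure_rois(st, rois)
    expect_equal(m$B, expected, tolerance = 1e-12)
  }
})

test_that("measurements are equivariant under joint integer translation", {
  set.seed(7)
  img <- matrix(runif(40 * 40, 0, 500), 40, 40)
  big <- matrix(0, 60, 60)
  big[6:45, 11:50] <- img  # shift by (dx = 10, dy = 5)
  poly <- random_polygon(30, 30) + 4
  m1 <- mean(img[polygon_mask(poly, c(40, 40))])
  m2 <- mean(big[polygon_mask(translate_polygon(poly, 10, 5), c(60, 60))])
  expect_identical(m1, m2)
})

test_that("degenerate ROIs and bounds raise errors", {
  st <- image_stack(list(matrix(1, 8, 8)), 0)
  thin <- cbind(x = c(0.2, 0.4, 0.3), y = c(0.2, 0.2, 0.4))  # no pixel center
  expect_error(
    roi_set(cells = list(c1 = list(list(stripe = thin,
                                        nucleus = rect_polygon(3, 3, 5, 5)))),
            background = list(rect_polygon(6, 6, 7, 7))),
    "empty ROI")
  out_of_bounds <- rect_polygon(5, 5, 12, 12)
  rois <- roi_set(cells = list(c1 = list(list(
    stripe = rect_polygon(0, 0, 2, 2), nucleus = rect_polygon(4, 0, 6, 2)))),
    background = list(out_of_bounds))
  expect_error(measure_rois(st, rois), "outside")
  # stripe overlapping the nucleus-remainder violates the disjointness rule
  expect_error(
    roi_set(cells = list(c1 = list(list(stripe = rect_polygon(0, 0, 4, 4),
                                        nucleus = rect_polygon(2, 2, 6, 6)))),
            background = list(rect_polygon(6, 6, 7, 7))),
    "overlap")
})

test_that("ROI JSON dialect round-trips", {
  rois <- roi_set(
    cells = list(a = list(list(stripe = rect_polygon(1, 1, 4, 2),
                               nucleus = rect_polygon(1, 4, 4, 6))),
                 b = list(list(stripe = rect_polygon(10, 1, 14, 2),
                               nucleus = rect_polygon(10, 4, 14, 6)))),
    background = list(rect_polygon(20, 20, 24, 24)))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_json(rois, path)
  rt <- read_roi_json(path)
  expect_identical(names(rt$cells), c("a", "b"))
  expect_equal(rt$cells$a[[1]]$stripe, rois$cells$a[[1]]$stripe)
  expect_equal(rt$background[[1]], rois$background[[1]])
})

test_that("ImageJ .roi polygon import reads a spec-conformant fixture", {
  # build a minimal big-endian polygon .roi (type 0) in code:
  # vertices (12,5), (20,5), (16,11) -> bounds top=5 left=12 bottom=12 right=21
  be16 <- function(x) {
    x <- as.integer(x); if (x < 0) x <- x + 65536L
    as.raw(c(x %/% 256L, x %% 256L))
  }
  buf <- c(charToRaw("Iout"), be16(228),            # magic, version
           as.raw(c(0L, 0L)),                       # type polygon, pad
           be16(5), be16(12), be16(12), be16(21),   # top left bottom right
           be16(3))                                 # n coordinates
  buf <- c(buf, rep(as.raw(0), 64 - length(buf)))
  buf <- c(buf, be16(0), be16(8), be16(4),          # x offsets from left
           be16(0), be16(0), be16(6))               # y offsets from top
  path <- withr::local_tempfile(fileext = ".roi")
  writeBin(buf, path)
  poly <- read_imagej_roi(path)
  expect_equal(poly, cbind(x = c(12, 20, 16), y = c(5, 5, 11)))
})

test_that("track_rois: identity, zero drift, and known linear drift", {
  # method "none" copies the t0 polygons verbatim
  sim0 <- simulate_stripe_movie(stripe_sim_config(
    n_cells = 2, image_dim = c(96L, 160L), timestamps = c(-5, 30, 60, 90),
    seed = 5))
  rois1 <- roi_set(cells = lapply(sim0$rois$cells, function(cf) cf[1]),
                   background = sim0$rois$background[1], validate = FALSE)
  none <- track_rois(sim0$stack, rois1, method = "none")
  expect_equal(none$cells[[1]][[4]], rois1$cells[[1]][[1]])

  # zero drift: estimated shifts all (0, 0)
  xc0 <- track_rois(sim0$stack, rois1, method = "xcorr", search = 4)
  expect_equal(xc0$cells[[1]][[4]]$stripe, rois1$cells[[1]][[1]]$stripe)

  # integer drift (1, 0) px/frame, noiseless: cumulative shift is exact
  cfg <- stripe_sim_config(n_cells = 1, image_dim = c(96L, 200L),
                           timestamps = c(-5, seq(10, 100, by = 10)),
                           drift = c(1, 0), poisson_noise = FALSE,
                           read_sd = 0, seed = 2)
  sim <- simulate_stripe_movie(cfg)
  r1 <- roi_set(cells = lapply(sim$rois$cells, function(cf) cf[1]),
                background = sim$rois$background[1], validate = FALSE)
  tracked <- track_rois(sim$stack, r1, method = "xcorr", search = 3)
  shift10 <- tracked$cells[[1]][[11]]$stripe - r1$cells[[1]][[1]]$stripe
  expect_equal(unique(shift10[, "x"]), 10)
  expect_equal(unique(shift10[, "y"]), 0)
})
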