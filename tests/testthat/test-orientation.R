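flat_path <- function(role, y, x = 0:299) apo_path(role, x, rep(y, length(x)))

test_that("ROIs overlap and tile the inter-aponeurosis field", {
  sup <- flat_path("superficial", 50)
  deep <- flat_path("deep", 200)
  rois <- define_rois(c(260, 300), sup, deep, n_rois = 3,
                      roi_width_pct = 60, roi_height_pct = 90)
  lefts <- vapply(rois, function(r) r$x, integer(1))
  # left edges at i * (W - w) / (n - 1): 0, 60, 120 for W=300, w=180
  expect_equal(lefts, c(0L, 60L, 120L))
  expect_true(all(vapply(rois, function(r) r$w, integer(1)) == 180L))
  # adjacent ROIs overlap by w - spacing = 120 px
  expect_equal(rois[[2]]$x - rois[[1]]$x, 60L)
  # two ROIs at 60% width always overlap
  rois2 <- define_rois(c(260, 300), sup, deep, n_rois = 2,
                       roi_width_pct = 60)
  expect_lt(rois2[[2]]$x, rois2[[1]]$x + rois2[[1]]$w)
  # ROIs exclude the aponeuroses plus the safety margin
  for (r in rois) {
    expect_gte(r$y, 50 + 6)
    expect_lte(r$y + r$h, 200 - 6 + 1)
  }
  # full-height request spans the gap minus margins
  roi_full <- define_rois(c(260, 300), sup, deep, n_rois = 1,
                          roi_height_pct = 100)[[1]]
  expect_equal(roi_full$h, 150L - 2L * 6L, tolerance = 1)
  # a collapsed gap is rejected
  expect_error(define_rois(c(260, 300), flat_path("superficial", 100),
                           flat_path("deep", 115), n_rois = 1),
               class = "sma_roi_too_small")
})

test_that("dominant orientation recovers grating angles and flags flat ROIs", {
  r <- dominant_orientation(make_grating(20, n = 96, period = 10), sigma = 4)
  expect_lt(abs(r$dominant_angle_deg - 20), 0.5)
  expect_gt(r$coherency, 0.9)
  expect_true(r$valid)
  # constant ROI: undefined angle, zero coherency, invalid
  rc <- dominant_orientation(matrix(0.3, 64, 64), sigma = 4)
  expect_false(rc$valid)
  expect_equal(rc$coherency, 0)
  expect_true(is.na(rc$dominant_angle_deg))
  expect_error(dominant_orientation(make_grating(20), sigma = -1),
               class = "sma_validation")
})

test_that("white-noise ROIs score near-isotropic coherency", {
  set.seed(42)
  for (i in 1:4) {
    nz <- matrix(runif(96 * 96), 96, 96)
    expect_lt(dominant_orientation(nz, sigma = 4)$coherency, 0.1)
  }
})

test_that("orientation is rotation-equivariant on noise-free gratings", {
  base <- 20
  for (d in c(-15, -10, 5, 10, 15)) {
    a0 <- dominant_orientation(make_grating(base, n = 96, period = 10),
                               sigma = 4, preprocess = FALSE)
    a1 <- dominant_orientation(make_grating(base + d, n = 96, period = 10),
                               sigma = 4, preprocess = FALSE)
    expect_lt(abs((a1$dominant_angle_deg - a0$dominant_angle_deg) - d), 0.5)
  }
})

test_that("speckle lowers the coherency of a grating", {
  g <- make_grating(20, n = 96, period = 10)
  set.seed(8)
  gs <- pmin(pmax(g * (1 + 0.3 * matrix(rnorm(96 * 96), 96, 96)), 0), 1)
  c0 <- dominant_orientation(g, sigma = 4)$coherency
  c1 <- dominant_orientation(gs, sigma = 4)$coherency
  expect_true(c0 >= 0 && c0 <= 1 && c1 >= 0 && c1 <= 1)
  expect_gt(c0, c1)
})

test_that("structure tensor matches the exhaustive FFT moment oracle", {
  set.seed(99)
  for (i in 1:20) {
    phi <- runif(1, -75, 75)
    period <- runif(1, 6, 12)
    g <- make_grating(phi, n = 64, period = period)
    st <- dominant_orientation(g, sigma = 4, preprocess = FALSE)
    or <- fft_orientation_oracle(g)
    expect_lt(abs(st$dominant_angle_deg - or), 1)
  }
})

test_that("sigma sweep reports the 0..7 table and the monotone-rise warning", {
  g <- make_grating(20, n = 96, period = 10)
  tab <- sigma_sweep(g)
  expect_equal(tab$sigma, 0:7)          # sigma = 0 row included
  a <- tab$dominant_angle_deg
  expect_lt(max(a[tab$sigma >= 1]) - min(a[tab$sigma >= 1]), 1)
  expect_false(attr(tab, "warning_flag"))
  # the flag is exactly the strict-monotone-increase criterion
  set.seed(5)
  nz <- matrix(runif(96 * 96), 96, 96)
  tn <- sigma_sweep(nz)
  an <- tn$dominant_angle_deg[tn$sigma >= 1]
  expect_identical(attr(tn, "warning_flag"), all(diff(an) > 0))
})

test_that("ROI angles aggregate by greatest, mean or median", {
  expect_equal(aggregate_angles(c(10, 12, 14), "mean"), 12)
  expect_equal(aggregate_angles(c(10, 12, 20), "median"), 12)
  expect_equal(aggregate_angles(c(10, 12, 20), "greatest"), 20)
  expect_equal(aggregate_angles(c(10, NA, 20), "mean"), 15)
  expect_error(aggregate_angles(numeric(0), "mean"),
               class = "sma_no_fascicle_orientation")
  expect_error(aggregate_angles(NA_real_, "median"),
               class = "sma_no_fascicle_orientation")
})
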