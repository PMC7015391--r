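test_that("total-least-squares line fit reports aponeurosis angles", {
  f <- fit_line(c(0, 10, 20), c(100, 100, 100))
  expect_equal(unname(f["angle_deg"]), 0)
  expect_equal(unname(f["intercept_px"]), 100)
  # descending-left-positive convention: a line rising to the right by
  # 10 px over 100 px rises toward the left, so its angle is negative
  f2 <- fit_line(c(0, 100), c(100, 110))
  expect_equal(unname(f2["angle_deg"]), -atan(10 / 100) * 180 / pi,
               tolerance = 1e-9)
  # noisy points around a known line recover the angle within 0.2 degrees
  set.seed(31)
  x <- 0:200
  y <- 50 + 0.05 * x + rnorm(201, sd = 0.5)
  f3 <- fit_line(x, y)
  expect_lt(abs(unname(f3["angle_deg"]) - (-atan(0.05) * 180 / pi)), 0.2)
  expect_error(fit_line(1, 1), class = "sma_validation")
})

test_that("extrapolation uses detected points inside support, the line outside", {
  p <- apo_path("superficial", x = 10:110, y = rep(100, 101))
  expect_equal(extrapolate(p, 50), 100)
  expect_equal(extrapolate(p, -50), 100)
  # a 5-degree line, evaluated beyond its support
  slope <- -tan(5 * pi / 180)
  p2 <- apo_path("deep", x = 0:100, y = 200 + slope * (0:100))
  expect_equal(p2$line_angle_deg, 5, tolerance = 1e-6)
  expect_equal(extrapolate(p2, 300), 200 + slope * 300, tolerance = 1e-6)
  # inside support the detected (here wiggly) point wins over the fit
  yw <- rep(100, 101); yw[51] <- 103
  p3 <- apo_path("superficial", x = 0:100, y = yw)
  expect_equal(extrapolate(p3, 50), 103)
})

test_that("edge chains register as depth-ordered near-horizontal candidates", {
  em <- matrix(FALSE, 100, 200)
  em[30, ] <- TRUE
  em[70, ] <- TRUE
  cands <- register_parallel_lines(em)
  expect_length(cands, 2)
  expect_equal(mean(cands[[1]]$y), 29)   # 0-based, depth order
  expect_equal(mean(cands[[2]]$y), 69)
  # scattered clutter is rejected by the span filter
  em2 <- matrix(FALSE, 100, 200)
  em2[45, ] <- TRUE
  set.seed(2)
  em2[cbind(sample(1:40, 30, TRUE), sample(1:200, 30, TRUE))] <- TRUE
  cands2 <- register_parallel_lines(em2)
  expect_length(cands2, 1)
  expect_equal(mean(cands2[[1]]$y), 44)
  # blank map: empty list
  expect_length(register_parallel_lines(matrix(FALSE, 50, 50)), 0)
  # lateral gaps up to the tolerance are bridged into one chain
  em3 <- matrix(FALSE, 100, 200)
  em3[50, c(1:95, 104:200)] <- TRUE
  expect_length(register_parallel_lines(em3, gap_tol = 10L), 1)
})

test_that("aponeuroses are recovered within 1 degree and 3 px on phantoms", {
  ph <- quick_phantom(sup_apo_angle_deg = 0, deep_apo_angle_deg = 0,
                      thickness_px = 140, speckle_sigma = 0.15, seed = 3L)
  paths <- detect_aponeuroses(ph$image)
  expect_lt(abs(paths$superficial$line_angle_deg), 1)
  expect_lt(abs(paths$deep$line_angle_deg), 1)
  # muscle-facing edges: lower edge of the superficial band, upper edge
  # of the deep band (sup centre 60, band 8, gap 140)
  expect_lt(abs(paths$superficial$line_intercept_px - 64), 3)
  expect_lt(abs(paths$deep$line_intercept_px - 204), 3)
  # an angled deep aponeurosis
  ph2 <- quick_phantom(deep_apo_angle_deg = 5, thickness_px = 150,
                       speckle_sigma = 0.15, seed = 13L)
  paths2 <- detect_aponeuroses(ph2$image)
  expect_lt(abs(paths2$deep$line_angle_deg - 5), 1)
})

test_that("deep path lies below superficial over a phantom grid", {
  for (a in c(-8, 0, 8)) for (th in c(60, 240)) {
    ph <- quick_phantom(deep_apo_angle_deg = a, sup_apo_angle_deg = -a / 2,
                        thickness_px = th, speckle_sigma = 0.2,
                        sup_apo_depth_px = 80, seed = 17L)
    paths <- detect_aponeuroses(ph$image)
    xs <- seq(max(paths$superficial$x_extent[1], paths$deep$x_extent[1]),
              min(paths$superficial$x_extent[2], paths$deep$x_extent[2]))
    expect_true(all(extrapolate(paths$deep, xs) >
                      extrapolate(paths$superficial, xs)))
    expect_lt(abs(paths$deep$line_angle_deg - a), 1)
    expect_lt(abs(paths$superficial$line_angle_deg - (-a / 2)), 1)
  }
})

test_that("recovered angles are stable across tubeness sigma 8 to 14", {
  ph <- quick_phantom(fascicle_angle_deg = 20, thickness_px = 140,
                      speckle_sigma = 0.15, seed = 6L)
  p8 <- detect_aponeuroses(ph$image, tubeness_sigma = 8)
  p14 <- detect_aponeuroses(ph$image, tubeness_sigma = 14)
  expect_lt(abs(p8$superficial$line_angle_deg -
                  p14$superficial$line_angle_deg), 1)
  expect_lt(abs(p8$deep$line_angle_deg - p14$deep$line_angle_deg), 1)
})

test_that("a weakly contrasted deep aponeurosis fails with actionable advice", {
  ph <- quick_phantom(deep_band_gain = 0.3, speckle_sigma = 0.15, seed = 2L)
  err <- expect_error(detect_aponeuroses(ph$image),
                      class = "sma_apo_not_found")
  expect_match(conditionMessage(err), "crop the image manually")
  expect_match(conditionMessage(err), "Tubeness sigma")
})
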