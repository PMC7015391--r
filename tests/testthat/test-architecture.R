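flat_path2 <- function(role, y, x = 0:299) apo_path(role, x, rep(y, length(x)))

test_that("pennation is the sum of the two inclinations and matches the vector oracle", {
  expect_equal(pennation_angle(15, 3), 18)
  expect_equal(pennation_angle(20, 0), 20)
  expect_equal(pennation_angle(20, -4), 16)
  # independent dot-product oracle, y pointing down
  vec_angle <- function(beta, alpha) {
    vf <- c(1, tan(beta * pi / 180)); va <- c(1, -tan(alpha * pi / 180))
    acos(sum(vf * va) / sqrt(sum(vf^2) * sum(va^2))) * 180 / pi
  }
  for (beta in c(5, 18, 40)) for (alpha in c(-6, 0, 7)) {
    # the oracle returns the unsigned angle between the lines
    expect_equal(abs(pennation_angle(beta, alpha)), vec_angle(beta, alpha),
                 tolerance = 1e-9)
  }
})

test_that("fascicle length follows the closed forms and analytic intersections", {
  sup <- flat_path2("superficial", 50)
  deep <- flat_path2("deep", 150)
  # gap 100, beta 30: chord = 100 / sin(30) = 200
  fl <- fascicle_length(sup, deep, 30, anchor_x = 250)
  expect_equal(fl$length_px, 200, tolerance = 1e-6)
  # near-vertical chord approaches the gap itself
  fl90 <- fascicle_length(sup, deep, 89.999, anchor_x = 150)
  expect_equal(fl90$length_px, 100, tolerance = 1e-3)
  # non-parallel lines against a brute-force three-line intersection
  alpha_d <- 4; alpha_s <- -2; beta <- 40
  ms <- -tan(alpha_s * pi / 180); md <- -tan(alpha_d * pi / 180)
  xs <- 0:400
  sup2 <- apo_path("superficial", xs, 80 + ms * xs)
  deep2 <- apo_path("deep", xs, 200 + md * xs)
  xa <- 200; ya <- 200 + md * xa
  mf <- tan(beta * pi / 180)
  xi <- (ya - mf * xa - 80) / (ms - mf); yi <- 80 + ms * xi
  want <- sqrt((xi - xa)^2 + (yi - ya)^2)
  got <- fascicle_length(sup2, deep2, beta, anchor_x = xa)
  expect_equal(got$length_px, want, tolerance = 1e-6)
  expect_false(got$extrapolated)
  # parallel chord and superficial line cannot intersect
  par <- apo_path("superficial", xs, 80 + tan(10 * pi / 180) * xs)
  expect_error(fascicle_length(par, deep2, 10, anchor_x = 200),
               class = "sma_error")
})

test_that("chord leaving the field of view is flagged as extrapolated", {
  ph <- quick_phantom(fascicle_angle_deg = 12, thickness_px = 160,
                      speckle_sigma = 0.1, width_px = 400L, seed = 21L)
  res <- analyse_image(ph$image, sma_config(crop = "none"))
  expect_true(res$extrapolated)  # run ~ 160/tan(12) = 750 px > 400 px wide
  expect_lt(abs(res$fascicle_length_px - ph$truth$true_fascicle_length_px) /
              ph$truth$true_fascicle_length_px, 0.05)
})

test_that("thickness is the mean per-column inter-aponeurosis distance", {
  expect_equal(muscle_thickness(flat_path2("superficial", 50),
                                flat_path2("deep", 150)), 100)
  # converging linearly from 120 to 80: mean gap is the midpoint value
  xs <- 0:299
  sup <- apo_path("superficial", xs, rep(50, 300))
  deep <- apo_path("deep", xs, 170 - (40 / 299) * xs)
  expect_equal(muscle_thickness(sup, deep), 100, tolerance = 1e-9)
  # disjoint supports are an error
  expect_error(muscle_thickness(flat_path2("superficial", 50, x = 0:99),
                                flat_path2("deep", 150, x = 200:299)),
               class = "sma_validation")
})

test_that("end-to-end phantom analysis recovers the architecture", {
  ph <- quick_phantom(fascicle_angle_deg = 20, thickness_px = 120,
                      speckle_sigma = 0.15, seed = 23L)
  res <- analyse_image(ph$image, sma_config(crop = "none"))
  expect_lt(abs(res$pennation_deg - 20), 2)
  expect_lt(abs(res$thickness_px - ph$truth$true_thickness_px), 4)
  expect_lt(abs(res$fascicle_length_px - ph$truth$true_fascicle_length_px) /
              ph$truth$true_fascicle_length_px, 0.05)
  # chord inequality holds on every analysis
  expect_gte(res$fascicle_length_px, res$thickness_px)
  # reported pennation equals the sum convention against its parts
  expect_equal(res$pennation_deg,
               res$fascicle_angle_deg + res$deep_apo_angle_deg)
})

test_that("repeated analysis of the same scan is bit-identical", {
  ph <- quick_phantom(speckle_sigma = 0.2, seed = 29L)
  r1 <- analyse_image(ph$image, sma_config(crop = "none"))
  r2 <- analyse_image(ph$image, sma_config(crop = "none"))
  expect_identical(r1, r2)
})

test_that("horizontal flip of a mirrored scan reproduces the original analysis", {
  ph <- quick_phantom(speckle_sigma = 0.15, seed = 31L)
  m <- raster_of(ph$image)
  mirrored <- m[, rev(seq_len(ncol(m)))]
  r0 <- analyse_image(ph$image, sma_config(crop = "none", flip = FALSE))
  r1 <- analyse_image(us_image(mirrored), sma_config(crop = "none",
                                                     flip = TRUE))
  expect_equal(r1$pennation_deg, r0$pennation_deg, tolerance = 1e-6)
  expect_equal(r1$fascicle_length_px, r0$fascicle_length_px,
               tolerance = 1e-6)
  expect_equal(r1$thickness_px, r0$thickness_px, tolerance = 1e-6)
})

test_that("calibration scales lengths linearly", {
  ph <- quick_phantom(speckle_sigma = 0.1, seed = 37L)
  c1 <- analyse_image(ph$image, sma_config(crop = "none", mm_per_px = 0.1))
  expect_equal(c1$thickness_mm, 0.1 * c1$thickness_px)
  expect_equal(c1$fascicle_length_mm, 0.1 * c1$fascicle_length_px)
})
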