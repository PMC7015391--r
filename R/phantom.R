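# Synthetic B-mode-like phantom generator. Every downstream stage of
# the pipeline is validated against these images because their
# architecture is known analytically.
#
# Geometry conventions (y increases downward, x to the right, proximal
# side on the left):
#   * aponeurosis angles (alpha) are positive when the line DESCENDS
#     toward the left, i.e. centreline y(x) = y0 - tan(alpha) * (x - xc);
#   * fascicle angles (beta) are positive when the striations RISE
#     toward the left, i.e. stripe slope dy/dx = +tan(beta);
#   * `thickness_px` is the vertical distance between the muscle-facing
#     band edges (lower edge of the superficial band, upper edge of the
#     deep band) at mid-width -- the quantity the pipeline measures as
#     muscle thickness.

#' Specify a synthetic ultrasound phantom
#'
#' Collects the full ground-truth geometry and noise parameters for one
#' synthetic scan: two bright near-horizontal aponeurosis bands, an
#' oblique rectified-sinusoid fascicle texture between them,
#' multiplicative speckle, and optionally an information frame (dark
#' border with text-like clutter and a tick-marked scale bar) around the
#' field of view.
#'
#' @param width_px,height_px image size in pixels.
#' @param sup_apo_angle_deg,deep_apo_angle_deg aponeurosis centreline
#'   angles from horizontal; positive descends toward the left.
#' @param sup_apo_depth_px depth of the superficial band centreline at
#'   mid-width (field-of-view coordinates).
#' @param thickness_px vertical distance between the muscle-facing band
#'   edges at mid-width.
#' @param apo_band_px aponeurosis band thickness (>= 2).
#' @param fascicle_angle_deg fascicle inclination from horizontal in
#'   (0, 90); positive rises toward the left.
#' @param fascicle_period_px stripe spacing measured perpendicular to
#'   the stripes (>= 4).
#' @param speckle_sigma multiplicative speckle strength (>= 0).
#' @param frame embed the field of view in an information frame?
#' @param scale_mm_per_px optional ground-truth calibration; when given
#'   and `frame = TRUE`, the scale bar carries ticks every 4 mm.
#' @param deep_band_gain intensity of the deep band relative to the
#'   superficial one (lowering it emulates a poorly contrasted deep
#'   aponeurosis, a designed failure mode).
#' @param seed integer RNG seed; identical (spec, seed) pairs produce
#'   bit-identical images.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_px = 512L, height_px = 400L,
                         sup_apo_angle_deg = 0, deep_apo_angle_deg = 0,
                         sup_apo_depth_px = 60, thickness_px = 140,
                         apo_band_px = 8, fascicle_angle_deg = 20,
                         fascicle_period_px = 14, speckle_sigma = 0.15,
                         frame = FALSE, scale_mm_per_px = NULL,
                         deep_band_gain = 1, seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               sup_apo_angle_deg = sup_apo_angle_deg,
               deep_apo_angle_deg = deep_apo_angle_deg,
               sup_apo_depth_px = sup_apo_depth_px,
               thickness_px = thickness_px,
               apo_band_px = apo_band_px,
               fascicle_angle_deg = fascicle_angle_deg,
               fascicle_period_px = fascicle_period_px,
               speckle_sigma = speckle_sigma,
               frame = isTRUE(frame),
               scale_mm_per_px = scale_mm_per_px,
               deep_band_gain = deep_band_gain,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    assert_that(width_px > 0 && height_px > 0, "validation",
                "phantom: image dimensions must be positive")
    assert_that(sup_apo_depth_px > 0, "validation",
                "phantom: sup_apo_depth_px must be > 0")
    assert_that(sup_apo_depth_px + thickness_px < height_px, "validation",
                "phantom: sup_apo_depth_px + thickness_px must fit inside height_px")
    assert_that(fascicle_angle_deg > 0 && fascicle_angle_deg < 90,
                "validation", "phantom: fascicle_angle_deg must lie in (0, 90)")
    assert_that(apo_band_px >= 2, "validation",
                "phantom: apo_band_px must be >= 2")
    assert_that(fascicle_period_px >= 4, "validation",
                "phantom: fascicle_period_px must be >= 4")
    assert_that(speckle_sigma >= 0, "validation",
                "phantom: speckle_sigma must be >= 0")
    assert_that(abs(sup_apo_angle_deg) < 45 && abs(deep_apo_angle_deg) < 45,
                "validation", "phantom: aponeurosis angles must be near-horizontal (|angle| < 45)")
  })
  invisible(spec)
}

# frame margins (px) when frame = TRUE; the right margin leaves room
# for the scale bar.
phantom_margins <- function() c(left = 40L, right = 56L, top = 40L, bottom = 40L)

# Analytic line descriptions of the muscle-facing band edges in
# field-of-view coordinates (0-based x).
phantom_edge_lines <- function(spec, fov_w) {
  xc <- (fov_w - 1) / 2
  ts <- tan(spec$sup_apo_angle_deg * pi / 180)
  td <- tan(spec$deep_apo_angle_deg * pi / 180)
  sup_c0 <- spec$sup_apo_depth_px
  sup_lower0 <- sup_c0 + spec$apo_band_px / 2
  deep_upper0 <- sup_lower0 + spec$thickness_px
  deep_c0 <- deep_upper0 + spec$apo_band_px / 2
  list(xc = xc,
       sup_center = function(x) sup_c0 - ts * (x - xc),
       sup_lower = function(x) sup_lower0 - ts * (x - xc),
       deep_center = function(x) deep_c0 - td * (x - xc),
       deep_upper = function(x) deep_upper0 - td * (x - xc))
}

#' Generate a synthetic ultrasound phantom
#'
#' Renders the image described by a [phantom_spec()] and computes its
#' analytic ground truth. The fascicle texture is a rectified sinusoid
#' (bright ridges separated by `fascicle_period_px`), so ridge filters
#' respond to it the way they respond to real fascicles; speckle is
#' multiplicative (`pixel * (1 + N(0, speckle_sigma))`, clipped).
#'
#' @param spec a [phantom_spec()].
#' @return a list with components `image` (a [us_image()]) and `truth`
#'   (class `phantom_truth`: `true_pennation_deg`,
#'   `true_fascicle_length_px`, `true_thickness_px`, `fov_rect`, and the
#'   edge-line parameters used to derive them).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)

  if (spec$frame) {
    mg <- phantom_margins()
    fov_w <- spec$width_px - mg[["left"]] - mg[["right"]]
    fov_h <- spec$height_px - mg[["top"]] - mg[["bottom"]]
    fov_x <- mg[["left"]]; fov_y <- mg[["top"]]
  } else {
    fov_w <- spec$width_px; fov_h <- spec$height_px
    fov_x <- 0L; fov_y <- 0L
  }
  assert_that(spec$sup_apo_depth_px + spec$thickness_px +
                spec$apo_band_px < fov_h, "validation",
              "phantom: geometry does not fit inside the field of view")

  lines <- phantom_edge_lines(spec, fov_w)
  xs <- matrix(rep(seq_len(fov_w) - 1, each = fov_h), fov_h, fov_w)
  ys <- matrix(rep(seq_len(fov_h) - 1, times = fov_w), fov_h, fov_w)

  base <- 0.24
  fov <- matrix(base, fov_h, fov_w)

  # fascicle texture between the muscle-facing edges
  beta <- spec$fascicle_angle_deg * pi / 180
  phase <- 2 * pi * (ys - tan(beta) * xs) * cos(beta) / spec$fascicle_period_px
  ridges <- pmax(sin(phase), 0)^1.5
  sup_lower <- lines$sup_lower(xs)
  deep_upper <- lines$deep_upper(xs)
  inside <- ys > sup_lower + 1 & ys < deep_upper - 1
  fov[inside] <- 0.16 + 0.4 * ridges[inside]

  # aponeurosis bands: flat-topped superellipse profile around each
  # centreline, brighter than everything else
  band_half <- spec$apo_band_px / 2
  prof_sup <- exp(-((ys - lines$sup_center(xs)) / band_half)^6)
  prof_deep <- exp(-((ys - lines$deep_center(xs)) / band_half)^6)
  fov <- pmax(fov, 0.9 * prof_sup, 0.9 * spec$deep_band_gain * prof_deep)

  # multiplicative speckle (seeded, RNG state restored on exit)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  if (spec$speckle_sigma > 0) {
    fov <- fov * (1 + spec$speckle_sigma * matrix(stats::rnorm(fov_h * fov_w),
                                                  fov_h, fov_w))
  }
  fov <- clamp01(fov)

  if (spec$frame) {
    img <- matrix(0.02, spec$height_px, spec$width_px)
    img[fov_y + seq_len(fov_h), fov_x + seq_len(fov_w)] <- fov
    img <- add_frame_clutter(img, spec, fov_x, fov_y, fov_w, fov_h)
  } else {
    img <- fov
  }

  truth <- phantom_truth(spec, lines, fov_x, fov_y, fov_w, fov_h)
  list(image = us_image(img, mm_per_px = spec$scale_mm_per_px),
       truth = truth)
}

# Text-like glyph clutter in the top/bottom margins plus a tick-marked
# scale bar in the right margin. Uses the already-seeded RNG stream.
add_frame_clutter <- function(img, spec, fov_x, fov_y, fov_w, fov_h) {
  h <- nrow(img); w <- ncol(img)
  n_glyph <- 40L
  gx <- floor(stats::runif(n_glyph, 2, w - 6))
  gy_top <- floor(stats::runif(n_glyph / 2, 4, max(fov_y - 18, 5)))
  gy_bot <- floor(stats::runif(n_glyph / 2, min(fov_y + fov_h + 14, h - 8), h - 6))
  gy <- c(gy_top, gy_bot)
  gw <- sample(2:4, n_glyph, replace = TRUE)
  gh <- sample(2:3, n_glyph, replace = TRUE)
  for (i in seq_len(n_glyph)) {
    rr <- gy[i] + seq_len(gh[i]); cc <- gx[i] + seq_len(gw[i])
    rr <- rr[rr >= 1 & rr <= h]; cc <- cc[cc >= 1 & cc <= w]
    img[rr, cc] <- 0.85
  }
  # vertical scale bar with ticks every 4 mm (or every 50 px uncalibrated)
  bar_x <- min(fov_x + fov_w + 20L, w - 4L)
  tick_px <- if (!is.null(spec$scale_mm_per_px))
    round(4 / spec$scale_mm_per_px) else 50L
  ys <- seq.int(fov_y, fov_y + fov_h - 1L, by = max(tick_px, 2L))
  img[fov_y + seq_len(fov_h) - 1L + 1L, bar_x] <- 0.6
  for (y in ys) img[y + 1L, pmin(bar_x + 0:3, w)] <- 0.95
  img
}

phantom_truth <- function(spec, lines, fov_x, fov_y, fov_w, fov_h) {
  beta <- spec$fascicle_angle_deg
  alpha_d <- spec$deep_apo_angle_deg
  true_pennation <- beta + alpha_d

  # composite fascicle anchored on the deep edge at mid-width
  xa <- lines$xc
  ya <- lines$deep_upper(xa)
  mf <- tan(beta * pi / 180)                  # fascicle slope dy/dx
  ms <- -tan(spec$sup_apo_angle_deg * pi / 180)  # superficial edge slope
  # intersect y = ya + mf (x - xa) with y = sup_lower(0) + ms x
  s0 <- lines$sup_lower(0)
  xi <- (ya - mf * xa - s0) / (ms - mf)
  yi <- s0 + ms * xi
  lf <- sqrt((xi - xa)^2 + (yi - ya)^2)

  # mean vertical edge gap across the FoV width (mean of a linear
  # function = its value at the mean x = xc)
  true_thickness <- lines$deep_upper(lines$xc) - lines$sup_lower(lines$xc)

  structure(list(true_pennation_deg = true_pennation,
                 true_fascicle_length_px = lf,
                 true_thickness_px = true_thickness,
                 fov_rect = fov_rect(fov_x, fov_y, fov_w, fov_h),
                 anchor = c(x = xa, y = ya),
                 insertion = c(x = xi, y = yi)),
            class = "phantom_truth")
}

#' Write a phantom image and its ground truth to disk
#'
#' Saves the rendered scan as an 8-bit grayscale PNG (or TIFF, by
#' extension) with a JSON sidecar holding the spec and analytic truth.
#'
#' @param phantom result of [generate_phantom()].
#' @param path output image path (`.png`, `.tif`/`.tiff`).
#' @param spec the [phantom_spec()] used (stored in the sidecar).
#' @return invisibly, the sidecar path.
#' @export
write_phantom <- function(phantom, path, spec = NULL) {
  write_image(phantom$image, path)
  sidecar <- paste0(tools::file_path_sans_ext(path), "_truth.json")
  truth <- unclass(phantom$truth)
  truth$fov_rect <- unclass(truth$fov_rect)
  jsonlite::write_json(list(spec = if (!is.null(spec)) unclass(spec),
                            truth = truth),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}
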