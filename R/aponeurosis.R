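# Segmentation and registration of the superficial and deep
# aponeuroses. The stage denoises, enhances near-horizontal ridges with
# tubeness, removes fascicle-direction energy in the frequency domain,
# detects band edges with a Canny detector and registers laterally
# contiguous edge chains into candidate lines; the muscle-facing edges
# of the top and bottom bands become the two aponeurosis paths.

#' Aponeurosis path
#'
#' Ordered per-column edge points of one aponeurosis (its muscle-facing
#' edge) together with a fitted line. Aponeurosis angles follow the
#' convention of the architecture stage: positive = the line descends
#' toward the left (y grows downward).
#'
#' @param role `"superficial"` or `"deep"`.
#' @param x,y pixel coordinates of the edge, one point per sampled
#'   column; `x` must be strictly increasing.
#' @return object of class `apo_path` with fields `role`, `x`, `y`,
#'   `line_angle_deg`, `line_intercept_px` (fitted y at x = 0) and
#'   `x_extent`.
#' @export
apo_path <- function(role = c("superficial", "deep"), x, y) {
  role <- match.arg(role)
  assert_that(length(x) == length(y) && length(x) >= 2, "validation",
              "apo_path: need >= 2 points")
  assert_that(all(diff(x) > 0), "validation",
              "apo_path: x must be strictly increasing")
  fit <- fit_line(x, y)
  structure(list(role = role, x = x, y = y,
                 line_angle_deg = fit[["angle_deg"]],
                 line_intercept_px = fit[["intercept_px"]],
                 x_extent = range(x)),
            class = "apo_path")
}

#' @export
print.apo_path <- function(x, ...) {
  cat(sprintf("apo_path (%s): angle %.2f deg, intercept %.1f px, x in [%d, %d] (%d points)\n",
              x$role, x$line_angle_deg, x$line_intercept_px,
              x$x_extent[1], x$x_extent[2], length(x$x)))
  invisible(x)
}

#' Total-least-squares line fit through edge points
#'
#' Fits the first principal axis of the (x, y) scatter and reports it as
#' an aponeurosis angle (degrees from horizontal, positive = descending
#' toward the left, i.e. `-atan(dy/dx)`) and the fitted y at x = 0.
#'
#' @param x,y coordinates (>= 2 points).
#' @return named vector `c(angle_deg, intercept_px)`.
#' @export
fit_line <- function(x, y) {
  assert_that(length(x) >= 2 && length(x) == length(y), "validation",
              "fit_line: need >= 2 points")
  cx <- mean(x); cy <- mean(y)
  cv <- stats::cov(cbind(x - cx, y - cy))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[1] < 0) v <- -v   # orient along +x
  if (abs(v[1]) < 1e-12) stop_sma("validation",
    "fit_line: points are vertical; no near-horizontal line")
  slope <- v[2] / v[1]
  c(angle_deg = -atan(slope) * 180 / pi,
    intercept_px = cy - slope * cx)
}

line_slope <- function(path) -tan(path$line_angle_deg * pi / 180)

#' Evaluate an aponeurosis path at a horizontal position
#'
#' Inside the detected x-extent this returns the (interpolated) detected
#' edge; outside, the fitted line is extrapolated, which is what lets a
#' composite fascicle run beyond the field of view.
#'
#' @param path an [apo_path()].
#' @param x horizontal position(s), image coordinates.
#' @return y position(s) in pixels.
#' @export
extrapolate <- function(path, x) {
  stopifnot(inherits(path, "apo_path"))
  inside <- x >= path$x_extent[1] & x <= path$x_extent[2]
  out <- path$line_intercept_px + line_slope(path) * x
  if (any(inside)) {
    out[inside] <- stats::approx(path$x, path$y, xout = x[inside],
                                 rule = 2)$y
  }
  out
}

#' Register laterally contiguous edge chains as candidate lines
#'
#' Bridges lateral gaps up to `gap_tol` pixels, labels the connected
#' chains, reduces each to one point per column (mean y), and keeps the
#' near-horizontal chains (fitted |angle| < 45 degrees) spanning at
#' least `min_span_frac` of the image width -- the "parallel lines in
#' the horizontal direction" that typify aponeuroses. Candidates are
#' returned ordered by depth (mean y).
#'
#' @param edge_map logical matrix of edge pixels.
#' @param gap_tol lateral gap bridged when chaining, in pixels.
#' @param min_span_frac minimum x-span as a fraction of the map width.
#' @return list of candidate data frames with columns `x`, `y` (possibly
#'   empty; the caller decides whether that is an error).
#' @export
register_parallel_lines <- function(edge_map, gap_tol = 10L,
                                    min_span_frac = 0.5) {
  stopifnot(is.matrix(edge_map))
  b <- edge_map > 0
  if (!any(b)) return(list())
  # Label the laterally dilated map (bridges gaps up to 2*gap_tol and
  # keeps stair-stepped oblique chains connected), then read the labels
  # back at the original edge pixels so positions are unchanged.
  lab_d <- from_ebi(EBImage::bwlabel(to_ebi(dilate_rows(b, gap_tol) * 1)))
  lab <- lab_d * b
  w <- ncol(b)
  cands <- list()
  for (k in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    xs <- idx[, 2]
    if ((max(xs) - min(xs) + 1) < min_span_frac * w) next
    yy <- tapply(idx[, 1], xs, mean)
    x <- as.integer(names(yy)) - 1L   # 0-based
    y <- as.numeric(yy) - 1
    if (length(x) < 2) next
    fit <- try(fit_line(x, y), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (abs(fit[["angle_deg"]]) >= 45) next
    cands[[length(cands) + 1L]] <- data.frame(x = x, y = y)
  }
  if (length(cands) == 0) return(list())
  cands[order(vapply(cands, function(d) mean(d$y), numeric(1)))]
}

# Sub-pixel re-localization of a near-horizontal edge: around each
# candidate point the vertical intensity gradient of the denoised image
# is searched for its extremum of the expected sign (falling for the
# lower edge of a bright band, rising for an upper edge), refined by a
# parabolic fit. Columns without a clear extremum keep the candidate y.
refine_edge_y <- function(den, x, y, falling, window) {
  sm <- gaussian_blur(den, 1)
  gy <- sep_convolve(sm, 1, c(-0.5, 0, 0.5))
  if (falling) gy <- -gy
  nr <- nrow(gy)
  out <- y
  ok <- rep(FALSE, length(x))
  for (i in seq_along(x)) {
    ci <- x[i] + 1L
    lo <- max(2L, round(y[i]) + 1L - window)
    hi <- min(nr - 1L, round(y[i]) + 1L + window)
    if (hi <= lo) next
    seg <- gy[lo:hi, ci]
    k <- which.max(seg)
    if (seg[k] <= 0) next
    r <- lo + k - 1L
    g0 <- gy[r - 1L, ci]; g1 <- gy[r, ci]; g2 <- gy[r + 1L, ci]
    denom <- g0 - 2 * g1 + g2
    delta <- if (abs(denom) > 1e-12) 0.5 * (g0 - g2) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    out[i] <- (r - 1L) + delta
    ok[i] <- TRUE
  }
  list(y = out, ok = ok)
}

#' Detect the superficial and deep aponeuroses
#'
#' Full aponeurosis stage: denoise (heavy preset), tubeness at
#' `tubeness_sigma`, FFT, magnitude thresholding, directional masking of
#' fascicle-direction energy, inverse FFT, Canny edge detection and
#' chain registration. A simple contrast threshold then keeps the
#' candidate lines adjacent to a bright band; the topmost line with its
#' band above becomes the superficial path (its muscle-facing edge) and
#' the bottommost line with its band below the deep path. Intermediate
#' structures (septa, fat fascia) and frequency-domain ghost lines are
#' discarded. Edge positions are finally re-localized to sub-pixel
#' accuracy on the denoised image.
#'
#' @param fov_image cropped field-of-view image (matrix or [us_image()]).
#' @param tubeness_sigma tubeness scale in pixels (default 10; lower
#'   values such as 8 give crisper edges when contrast allows, higher
#'   values help weakly contrasted aponeuroses at the cost of slight
#'   edge distortion).
#' @param spectrum_threshold `"auto"` or a fraction in (0, 1].
#' @param mask_center_deg,mask_halfwidth_deg feature-angle wedge
#'   suppressed in the spectrum (default 10--80 degrees rising-left,
#'   the expected fascicle directions).
#' @param gap_tol,min_span_frac chain registration parameters, see
#'   [register_parallel_lines()].
#' @return list with elements `superficial` and `deep` ([apo_path()]s).
#' @export
detect_aponeuroses <- function(fov_image, tubeness_sigma = 10,
                               spectrum_threshold = "auto",
                               mask_center_deg = 45,
                               mask_halfwidth_deg = 35,
                               gap_tol = 10L, min_span_frac = 0.5) {
  assert_that(tubeness_sigma > 0, "validation",
              "detect_aponeuroses: tubeness_sigma must be > 0")
  m <- as_raster(fov_image)
  den <- denoise(m, "aponeurosis")
  tub <- tubeness(den, tubeness_sigma)
  mx <- max(tub)
  if (mx > 0) tub <- tub / mx
  ps <- power_spectrum(tub)
  ps <- threshold_spectrum(ps, spectrum_threshold)
  ps <- orientation_mask(ps, mask_center_deg, mask_halfwidth_deg)
  filt <- inverse_spectrum(ps)
  filt <- filt - min(filt)
  if (max(filt) > 0) filt <- filt / max(filt)
  edges <- canny_edges(filt, sigma = 1.4)
  cands <- register_parallel_lines(edges, gap_tol = gap_tol,
                                   min_span_frac = min_span_frac)
  if (length(cands) < 2) {
    stop_sma("apo_not_found", paste(
      "fewer than two aponeurosis lines detected;",
      "crop the image manually or use a higher value of Tubeness sigma"))
  }
  # Simple contrast threshold: an aponeurosis edge is adjacent to a
  # bright band, so score each candidate by the brightest image row just
  # above and just below the line (frequency-domain ringing produces
  # ghost lines in dark tissue, which this rejects). The muscle-facing
  # edge of the superficial aponeurosis has its band ABOVE, that of the
  # deep aponeurosis BELOW.
  side_brightness <- function(cand, side) {
    offs <- if (side == "above") -(1:6) else 1:6
    vals <- vapply(offs, function(o) {
      rr <- pmin(pmax(round(cand$y) + o + 1L, 1L), nrow(den))
      mean(den[cbind(rr, cand$x + 1L)])
    }, numeric(1))
    max(vals)
  }
  ba <- vapply(cands, side_brightness, numeric(1), side = "above")
  bb <- vapply(cands, side_brightness, numeric(1), side = "below")
  thr <- 0.5 * max(ba, bb)
  adj <- which(ba >= thr | bb >= thr)
  depths <- vapply(cands, function(d) mean(d$y), numeric(1))
  if (length(adj) < 2 || min(depths[adj]) >= max(depths[adj]) - 1) {
    stop_sma("apo_not_found", paste(
      "could not register two aponeuroses with sufficient contrast;",
      "crop the image manually or use a higher value of Tubeness sigma"))
  }
  i_sup <- adj[which.min(depths[adj])]
  i_deep <- adj[which.max(depths[adj])]
  sup_chain <- cands[[i_sup]]
  deep_chain <- cands[[i_deep]]
  # The Canny edge of the tubeness ridge is displaced outward by an
  # amount that grows with tubeness_sigma (the "slight distortion" of
  # high sigma values); re-localize each column on the denoised image,
  # where the band edge is a sharp intensity transition. When the
  # registered line is the far edge of its band (bright side away from
  # the muscle) the search window is shifted across the band so the
  # muscle-facing edge is found.
  win <- max(4, round(0.8 * tubeness_sigma))
  sup_off <- if (bb[i_sup] >= thr && ba[i_sup] < thr) win else 0L
  deep_off <- if (ba[i_deep] >= thr && bb[i_deep] < thr) -win else 0L
  sup_ref <- refine_edge_y(den, sup_chain$x, sup_chain$y + sup_off,
                           falling = TRUE, window = win)
  deep_ref <- refine_edge_y(den, deep_chain$x, deep_chain$y + deep_off,
                            falling = FALSE, window = win)
  keep_s <- sup_ref$ok; keep_d <- deep_ref$ok
  if (sum(keep_s) < 2 || sum(keep_d) < 2) {
    stop_sma("apo_not_found", paste(
      "aponeurosis edges could not be localized;",
      "crop the image manually or use a higher value of Tubeness sigma"))
  }
  sup <- apo_path("superficial", sup_chain$x[keep_s], sup_ref$y[keep_s])
  deep <- apo_path("deep", deep_chain$x[keep_d], deep_ref$y[keep_d])
  xs <- seq(max(sup$x_extent[1], deep$x_extent[1]),
            min(sup$x_extent[2], deep$x_extent[2]))
  if (length(xs) < 2 || any(extrapolate(deep, xs) <= extrapolate(sup, xs))) {
    stop_sma("apo_not_found", paste(
      "aponeurosis ordering violated (deep path not below superficial);",
      "crop the image manually or use a higher value of Tubeness sigma"))
  }
  list(superficial = sup, deep = deep)
}
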