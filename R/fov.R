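# Detection of the ultrasound field of view: scans nearly always carry
# an information frame (institution, settings, scale bar) around the
# image proper; this stage finds the field of view and crops it out of a
# duplicate, leaving the original untouched.

#' Pixel rectangle (0-based, top-left origin, half-open)
#'
#' @param x,y offsets of the top-left corner (0-based).
#' @param w,h extents in pixels (> 0).
#' @return object of class `fov_rect`.
#' @export
fov_rect <- function(x, y, w, h) {
  assert_that(x >= 0 && y >= 0 && w > 0 && h > 0, "validation",
              "fov_rect: x, y must be >= 0 and w, h > 0")
  structure(list(x = as.integer(round(x)), y = as.integer(round(y)),
                 w = as.integer(round(w)), h = as.integer(round(h))),
            class = "fov_rect")
}

#' @export
print.fov_rect <- function(x, ...) {
  cat(sprintf("fov_rect: x=%d y=%d w=%d h=%d\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' Detect the ultrasound field of view
#'
#' Suppresses frame text with a box-blur convolution and a median
#' filter, binarizes against a local-median threshold (a small offset
#' above the local median, or above an absolute brightness floor so a
#' frameless scan binarizes as one block), consolidates the result by
#' morphological closing, and returns the bounding rectangle of the
#' largest connected bright component. The input image is never
#' modified; all filtering happens on a duplicate.
#'
#' @param image grayscale image (matrix or [us_image()], \[0,1\]).
#' @param blur_size box-blur kernel width for text suppression.
#' @param median_radius median filter radius.
#' @param window_frac local-median window as a fraction of image height.
#' @param offset binarization offset above the local median.
#' @param bright_floor absolute brightness that always binarizes as
#'   foreground.
#' @param min_area_frac minimum fraction of the image area the detected
#'   rectangle must cover; below it a `sma_fov_not_found` error is
#'   raised advising manual cropping.
#' @return a [fov_rect()].
#' @export
detect_fov <- function(image, blur_size = 5L, median_radius = 3L,
                       window_frac = 1 / 8, offset = 0.04,
                       bright_floor = 0.15, min_area_frac = 0.2) {
  m <- as_raster(image)
  h <- nrow(m); w <- ncol(m)
  f <- box_blur(m, blur_size)
  f <- from_ebi(EBImage::medianFilter(to_ebi(clamp01(f)), size = median_radius))
  win <- max(9L, 2L * (round(window_frac * h) %/% 2L) + 1L)
  loc_med <- from_ebi(EBImage::medianFilter(to_ebi(clamp01(f)),
                                            size = (win - 1L) %/% 2L))
  b <- f > pmin(loc_med + offset, 1) | f > bright_floor
  # consolidate the speckle field into one component
  kern <- EBImage::makeBrush(9, shape = "disc")
  b <- from_ebi(EBImage::closing(to_ebi(b * 1), kern)) > 0.5
  lab <- from_ebi(EBImage::bwlabel(to_ebi(b * 1)))
  if (max(lab) < 1) stop_sma("fov_not_found",
    "no field of view detected; crop the image manually")
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2])
  rect <- fov_rect(x0, y0, x1 - x0, y1 - y0)
  if (rect$w * rect$h < min_area_frac * w * h) {
    stop_sma("fov_not_found", sprintf(
      "largest bright region (%d x %d px) covers less than %.0f%% of the image; no field of view found -- crop the image manually",
      rect$w, rect$h, 100 * min_area_frac))
  }
  rect
}

#' Crop an image to a rectangle
#'
#' Returns the sub-image; the input is not modified. In batch mode the
#' same rectangle is reused for every file.
#'
#' @param image grayscale image (matrix or [us_image()]).
#' @param rect a [fov_rect()] within the image bounds.
#' @return a [us_image()] of exactly the requested dimensions.
#' @export
crop <- function(image, rect) {
  stopifnot(inherits(rect, "fov_rect"))
  m <- as_raster(image)
  assert_that(rect$x + rect$w <= ncol(m) && rect$y + rect$h <= nrow(m),
              "validation", "crop: rectangle out of image bounds")
  us_image(m[rect$y + seq_len(rect$h), rect$x + seq_len(rect$w),
             drop = FALSE],
           mm_per_px = mm_per_px_of(image))
}
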