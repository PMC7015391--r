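# Image loading/saving, pixel-to-mm calibration, result serialization
# and overlay rendering.

#' Load a grayscale ultrasound image
#'
#' Reads PNG or TIFF directly; other formats are attempted through
#' EBImage. RGB input is converted to luma with the ITU-R BT.601
#' weights (0.299, 0.587, 0.114) for reproducibility.
#'
#' @param path image file path.
#' @param mm_per_px optional calibration attached to the image.
#' @return a [us_image()].
#' @export
load_image <- function(path, mm_per_px = NULL) {
  if (!file.exists(path)) {
    stop_sma("io", sprintf("cannot read image file '%s': no such file", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    aperm(EBImage::imageData(EBImage::readImage(path)))
  ), error = function(e) {
    stop_sma("io", sprintf("cannot read image file '%s': %s", path,
                           conditionMessage(e)))
  })
  m <- if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else arr[, , 1]
  } else arr
  us_image(clamp01(m), mm_per_px = mm_per_px)
}

#' Write a grayscale image as 8-bit PNG or TIFF
#'
#' @param image matrix or [us_image()] in \[0,1\].
#' @param path output path; format chosen by extension.
#' @return invisibly, `path`.
#' @export
write_image <- function(image, path) {
  m <- clamp01(as_raster(image))
  m <- round(m * 255) / 255   # quantize to 8-bit
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop_sma("io", sprintf("unsupported output format '%s'", ext)))
  invisible(path)
}

#' Pixel-to-millimetre calibration from a measured scale line
#'
#' Headless equivalent of drawing a line over the scale bar: the user
#' supplies the measured line length in pixels and the known physical
#' length.
#'
#' @param line_length_px measured length in pixels (> 0).
#' @param known_length_mm physical length in millimetres (> 0).
#' @param source provenance tag.
#' @return object of class `sma_calibration` with field `mm_per_px`.
#' @export
calibrate <- function(line_length_px, known_length_mm,
                      source = c("manual_line", "phantom_truth", "none")) {
  source <- match.arg(source)
  assert_that(is.numeric(line_length_px) && line_length_px > 0 &&
                is.numeric(known_length_mm) && known_length_mm > 0,
              "validation", "calibrate: lengths must be > 0")
  structure(list(mm_per_px = known_length_mm / line_length_px,
                 source = source),
            class = "sma_calibration")
}

#' Write the results table as CSV
#'
#' @param rows data frame, one row per analysed image.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Render an analysis overlay
#'
#' Draws the detected aponeurosis paths (green), the ROI rectangles
#' (yellow) and the composite fascicle line (red) on top of the cropped
#' field of view.
#'
#' @param fov_image the analysed field-of-view image.
#' @param result an `architecture_result`.
#' @return `h x w x 3` RGB array in \[0,1\].
#' @export
render_overlay <- function(fov_image, result) {
  m <- clamp01(as_raster(fov_image))
  rgb <- array(rep(m, 3), dim = c(nrow(m), ncol(m), 3))
  draw_px <- function(rgb, x, y, col) {
    ok <- x >= 0 & x < ncol(m) & y >= 0 & y < nrow(m)
    x <- round(x[ok]); y <- round(y[ok])
    for (ch in 1:3) rgb[cbind(y + 1L, x + 1L, ch)] <- col[ch]
    rgb
  }
  draw_seg <- function(rgb, p0, p1, col) {
    n <- max(2L, ceiling(2 * max(abs(p1 - p0))))
    t <- seq(0, 1, length.out = n)
    draw_px(rgb, p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]), col)
  }
  for (p in result$paths) {
    rgb <- draw_px(rgb, p$x, p$y, c(0, 1, 0))
  }
  for (r in result$rois) {
    xs <- seq(r$x, r$x + r$w - 1L); ys <- seq(r$y, r$y + r$h - 1L)
    rgb <- draw_px(rgb, xs, rep(r$y, length(xs)), c(1, 1, 0))
    rgb <- draw_px(rgb, xs, rep(r$y + r$h - 1L, length(xs)), c(1, 1, 0))
    rgb <- draw_px(rgb, rep(r$x, length(ys)), ys, c(1, 1, 0))
    rgb <- draw_px(rgb, rep(r$x + r$w - 1L, length(ys)), ys, c(1, 1, 0))
  }
  fl <- result$fascicle_line
  rgb <- draw_seg(rgb, fl$anchor, fl$insertion, c(1, 0, 0))
  rgb
}

#' Write a stack of overlay images as a multi-page TIFF
#'
#' @param images list of `h x w x 3` RGB arrays (or grayscale matrices).
#' @param path output `.tif` path.
#' @return invisibly, `path`.
#' @export
write_overlay_stack <- function(images, path) {
  assert_that(length(images) >= 1, "validation",
              "write_overlay_stack: need at least one image")
  tiff::writeTIFF(lapply(images, function(m) clamp01(m)),
                  path, bits.per.sample = 8L)
  invisible(path)
}
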