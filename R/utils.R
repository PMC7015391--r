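# Internal helpers: error conditions, image container, separable
# convolution and FFT index bookkeeping shared across the pipeline.

stop_sma <- function(subclass, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("sma_", subclass), "sma_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

assert_that <- function(ok, subclass, message) {
  if (!isTRUE(ok)) stop_sma(subclass, message)
}

#' Construct an ultrasound image object
#'
#' Wraps a 2D grayscale raster (numeric matrix, row = y from the top,
#' column = x from the left, intensities in \[0, 1\]) together with an
#' optional millimetre-per-pixel calibration.
#'
#' @param data numeric matrix of intensities in \[0, 1\].
#' @param mm_per_px optional calibration (millimetres per pixel), or `NULL`.
#' @return an object of class `us_image` (a matrix with attributes).
#' @export
us_image <- function(data, mm_per_px = NULL) {
  assert_that(is.matrix(data) && is.numeric(data), "validation",
              "image data must be a numeric matrix")
  if (!is.null(mm_per_px)) {
    assert_that(is.numeric(mm_per_px) && length(mm_per_px) == 1 &&
                  mm_per_px > 0, "validation", "mm_per_px must be > 0")
  }
  structure(data, mm_per_px = mm_per_px,
            class = c("us_image", class(data)))
}

as_raster <- function(img) {
  # strip class/attributes down to a plain matrix
  m <- unclass(img)
  attr(m, "mm_per_px") <- NULL
  class(m) <- NULL
  dim(m) <- dim(img)
  m
}

mm_per_px_of <- function(img) attr(img, "mm_per_px", exact = TRUE)

#' @export
print.us_image <- function(x, ...) {
  cal <- mm_per_px_of(x)
  cat(sprintf("us_image: %d x %d px, range [%.3f, %.3f]%s\n",
              ncol(x), nrow(x), min(x), max(x),
              if (is.null(cal)) "" else
                sprintf(", %.4f mm/px", cal)))
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Gaussian kernel (possibly a derivative) sampled on integer offsets.
gaussian_kernel <- function(sigma, order = 0, radius = NULL) {
  stopifnot(sigma > 0, order %in% 0:2)
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = {
           k <- (x^2 - sigma^2) / sigma^4 * g
           k - mean(k)   # exact zero response on constants
         })
}

# Replicate-pad a matrix by (ry, rx) on each side.
pad_replicate <- function(m, ry, rx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, ry), seq_len(nr), rep(nr, ry))
  ci <- c(rep(1L, rx), seq_len(nc), rep(nc, rx))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with replicate boundary handling. kx runs along
# x (columns), ky along y (rows). Kernels are centred, odd length.
sep_convolve <- function(m, kx, ky) {
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  p <- pad_replicate(m, ry, rx)
  nr <- nrow(m); nc <- ncol(m)
  # along x
  tmp <- matrix(0, nrow(p), nc)
  for (t in seq_along(kx)) {
    if (kx[t] != 0)
      tmp <- tmp + kx[t] * p[, seq.int(t, t + nc - 1L), drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (t in seq_along(ky)) {
    if (ky[t] != 0)
      out <- out + ky[t] * tmp[seq.int(t, t + nr - 1L), , drop = FALSE]
  }
  out
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  g <- gaussian_kernel(sigma)
  sep_convolve(m, g, g)
}

box_blur <- function(m, size = 5L) {
  k <- rep(1 / size, size)
  sep_convolve(m, k, k)
}

# Signed frequency index (cycles per image extent) for an FFT axis of
# length n: 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1.
fft_freq_index <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k > n / 2, k - n, k)
}

# Map an angle in degrees to the half-open interval (-90, 90].
wrap_angle_180 <- function(a) {
  a <- (a + 90) %% 180 - 90
  ifelse(a == -90, 90, a)
}

# Smallest angular distance between two feature angles (mod 180).
angdiff_180 <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# EBImage round-trips: EBImage stores images [x, y], ours are [y, x].
to_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(e) t(EBImage::imageData(e))

# Per-row (along x) binary dilation / erosion with half-width r,
# used to bridge lateral gaps before connected-component labelling.
dilate_rows <- function(b, r) {
  out <- b
  nc <- ncol(b)
  for (d in seq_len(r)) {
    out[, seq_len(nc - d)] <- out[, seq_len(nc - d)] |
      b[, seq.int(d + 1L, nc)]
    out[, seq.int(d + 1L, nc)] <- out[, seq.int(d + 1L, nc)] |
      b[, seq_len(nc - d)]
  }
  out
}

erode_rows <- function(b, r) {
  out <- b
  nc <- ncol(b)
  for (d in seq_len(r)) {
    out[, seq_len(nc - d)] <- out[, seq_len(nc - d)] &
      b[, seq.int(d + 1L, nc)]
    out[, seq.int(d + 1L, nc)] <- out[, seq.int(d + 1L, nc)] &
      b[, seq_len(nc - d)]
  }
  out
}
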