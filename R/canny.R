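# Canny edge detection: Gaussian smoothing, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, and
# hysteresis linking of weak edges to strong ones (via connected
# components). Hysteresis thresholds are derived from intensity
# percentiles of the non-zero gradient magnitudes, so the detector
# adapts to the dynamic range left after frequency-domain filtering.

sobel_gradients <- function(m) {
  gx <- sep_convolve(m, c(-1, 0, 1), c(1, 2, 1) / 4)
  gy <- sep_convolve(m, c(1, 2, 1) / 4, c(-1, 0, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Compare each pixel with its two neighbours along the gradient
# direction quantized to 0/45/90/135 degrees.
nonmax_suppress <- function(mag, gx, gy) {
  nr <- nrow(mag); nc <- ncol(mag)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
            ifelse(ang < 67.5, 1L, ifelse(ang < 112.5, 2L, 3L)))
  p <- pad_replicate(mag, 1L, 1L)
  ri <- seq_len(nr) + 1L; ci <- seq_len(nc) + 1L
  shift <- function(dy, dx) p[ri + dy, ci + dx]
  n1 <- matrix(0, nr, nc); n2 <- n1
  # sector 0: gradient ~horizontal -> compare left/right neighbours
  sel <- sector == 0L; n1[sel] <- shift(0L, -1L)[sel]; n2[sel] <- shift(0L, 1L)[sel]
  # sector 1: diagonal (gx, gy same sign in screen coords)
  sel <- sector == 1L; n1[sel] <- shift(-1L, -1L)[sel]; n2[sel] <- shift(1L, 1L)[sel]
  # sector 2: gradient ~vertical -> compare up/down
  sel <- sector == 2L; n1[sel] <- shift(-1L, 0L)[sel]; n2[sel] <- shift(1L, 0L)[sel]
  # sector 3: anti-diagonal
  sel <- sector == 3L; n1[sel] <- shift(-1L, 1L)[sel]; n2[sel] <- shift(1L, -1L)[sel]
  mag >= n1 & mag > n2 & mag > 0
}

#' Canny edge detector
#'
#' @param img numeric matrix.
#' @param sigma Gaussian smoothing scale before differentiation.
#' @param low_q,high_q hysteresis thresholds as quantiles of the
#'   non-negligible gradient magnitudes.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1.4, low_q = 0.5, high_q = 0.85) {
  m <- as_raster(img)
  if (sigma > 0) m <- gaussian_blur(m, sigma)
  g <- sobel_gradients(m)
  nz <- g$mag[g$mag > 1e-6 * max(g$mag)]
  if (length(nz) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  th_high <- stats::quantile(nz, high_q, names = FALSE)
  th_low <- stats::quantile(nz, low_q, names = FALSE)
  keep <- nonmax_suppress(g$mag, g$gx, g$gy)
  strong <- keep & g$mag >= th_high
  weak <- keep & g$mag >= th_low
  if (!any(strong)) return(matrix(FALSE, nrow(m), ncol(m)))
  lab <- from_ebi(EBImage::bwlabel(to_ebi(weak * 1)))
  good <- unique(lab[strong])
  good <- good[good > 0]
  weak & matrix(lab %in% good, nrow(lab), ncol(lab))
}
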