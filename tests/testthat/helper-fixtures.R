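# Shared fixtures, all generated in code.

# Oblique sinusoidal grating: stripes at feature angle phi_deg
# (positive = rising toward the left, y down), perpendicular spacing
# `period` pixels.
make_grating <- function(phi_deg, n = 64, period = 8, nr = n, nc = n) {
  phi <- phi_deg * pi / 180
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  0.5 + 0.5 * sin(2 * pi * (ys - tan(phi) * xs) * cos(phi) / period)
}

# Grating whose energy sits exactly on one FFT bin pair (ky, kx cycles
# per image), so spectral operations act on it without leakage.
# Its feature angle is atan2(ky / n, kx / n) - 90 (wrapped).
make_bin_grating <- function(ky, kx, n = 64) {
  xs <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  ys <- matrix(rep(seq_len(n) - 1, times = n), n, n)
  0.5 + 0.4 * cos(2 * pi * (kx * xs + ky * ys) / n)
}

bin_feature_angle <- function(ky, kx) {
  a <- atan2(ky, kx) * 180 / pi - 90
  a <- (a + 90) %% 180 - 90
  if (a == -90) 90 else a
}

# Small default phantom used when the full-size study phantom is not
# needed; keeps the suite fast.
quick_phantom <- function(..., seed = 1L) {
  generate_phantom(phantom_spec(..., seed = seed))
}

raster_of <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(img))
  m
}

pearson <- function(a, b) stats::cor(as.numeric(a), as.numeric(b))

# Independent stripe-orientation oracle: locate the peak of the 2D FFT
# magnitude (Hann-windowed, DC neighbourhood excluded) and refine it by
# a magnitude-squared centroid over its 5x5 neighbourhood; return the
# corresponding feature angle in degrees.
fft_peak_angle <- function(m) {
  m <- m - mean(m)
  wy <- 0.5 - 0.5 * cospi(2 * (seq_len(nrow(m)) - 1) / (nrow(m) - 1))
  wx <- 0.5 - 0.5 * cospi(2 * (seq_len(ncol(m)) - 1) / (ncol(m) - 1))
  P <- Mod(stats::fft(m * outer(wy, wx)))^2
  nr <- nrow(P); nc <- ncol(P)
  fy <- sma:::fft_freq_index(nr) / nr
  fx <- sma:::fft_freq_index(nc) / nc
  R2 <- outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2)
  P[R2 < (3 / min(nr, nc))^2] <- 0   # drop the DC neighbourhood
  k <- which(P == max(P), arr.ind = TRUE)[1, ]
  iy <- ((k[1] - 1 + seq(-2, 2)) %% nr) + 1
  ix <- ((k[2] - 1 + seq(-2, 2)) %% nc) + 1
  W <- P[iy, ix]
  cy <- sum(W * outer(fy[iy], rep(1, 5))) / sum(W)
  cx <- sum(W * outer(rep(1, 5), fx[ix])) / sum(W)
  a <- atan2(cy, cx) * 180 / pi - 90
  a <- (a + 90) %% 180 - 90
  if (a <= -90) a + 180 else a
}
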