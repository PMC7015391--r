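# Spatial- and frequency-domain enhancement primitives shared by the
# aponeurosis and fascicle-orientation stages.

#' Hessian-based tubeness (ridge) filter
#'
#' Scores each pixel by the eigenvalues of the Gaussian-scale Hessian:
#' bright elongated ridges on a dark background produce a strongly
#' negative principal curvature across the ridge, so the response
#' `sigma^2 * max(-lambda_min, 0)` is positive and maximal along ridge
#' centrelines and near zero elsewhere. This is the standard 2D
#' vessel/ridge enhancement used to highlight aponeuroses (large sigma)
#' and fascicles (small sigma) in B-mode scans.
#'
#' @param img numeric matrix (grayscale image, \[0,1\]).
#' @param sigma scale of the Gaussian derivatives in pixels (> 0).
#' @return numeric matrix of non-negative ridge responses.
#' @export
tubeness <- function(img, sigma) {
  assert_that(is.numeric(sigma) && length(sigma) == 1 && sigma > 0,
              "validation", "tubeness: sigma must be a single value > 0")
  m <- as_raster(img)
  g0 <- gaussian_kernel(sigma, 0)
  g1 <- gaussian_kernel(sigma, 1)
  g2 <- gaussian_kernel(sigma, 2)
  ixx <- sep_convolve(m, g2, g0)
  iyy <- sep_convolve(m, g0, g2)
  ixy <- sep_convolve(m, g1, g1)
  # smaller (most negative) eigenvalue of [[ixx, ixy], [ixy, iyy]]
  tr2 <- (ixx + iyy) / 2
  disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  lmin <- tr2 - disc
  sigma^2 * pmax(-lmin, 0)
}

#' Centre-aware power spectrum of an image
#'
#' Computes the 2D FFT and keeps the complex coefficients together with
#' the image's mean brightness (used by the automatic spectrum
#' threshold). The inverse transform of an unmodified spectrum
#' reconstructs the input to floating-point accuracy.
#'
#' @param img numeric matrix.
#' @return object of class `power_spectrum`.
#' @export
power_spectrum <- function(img) {
  m <- as_raster(img)
  structure(list(F = stats::fft(m), nr = nrow(m), nc = ncol(m),
                 mean_brightness = mean(m)),
            class = "power_spectrum")
}

#' Inverse FFT of a (possibly filtered) power spectrum
#'
#' @param ps a `power_spectrum`.
#' @return numeric matrix (real part of the inverse transform).
#' @export
inverse_spectrum <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  Re(stats::fft(ps$F, inverse = TRUE)) / (ps$nr * ps$nc)
}

#' Log-magnitude raster of a power spectrum (centre-shifted)
#'
#' Diagnostic view with the DC term at the centre, as spectra are
#' conventionally displayed.
#'
#' @param ps a `power_spectrum`.
#' @return numeric matrix of `log1p` magnitudes, DC central.
#' @export
spectrum_magnitude <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  m <- log1p(Mod(ps$F))
  sy <- floor(ps$nr / 2); sx <- floor(ps$nc / 2)
  m[c(seq.int(sy + 1L, ps$nr), seq_len(sy)),
    c(seq.int(sx + 1L, ps$nc), seq_len(sx))]
}

#' Threshold a power spectrum by magnitude
#'
#' Zeroes all frequency bins whose log-magnitude falls below a fraction
#' of the maximum log-magnitude, retaining only the dominant periodic
#' signal (aponeuroses, fascicles). With `threshold = "auto"` the
#' fraction is proportional to the mean brightness of the originating
#' image (`auto_k * mean`, clipped to \[0.05, 0.9\]). The DC component is
#' always retained so the mean level survives.
#'
#' @param ps a `power_spectrum`.
#' @param threshold fraction in (0, 1\] or `"auto"`.
#' @param auto_k proportionality constant for the automatic mode.
#' @return a filtered `power_spectrum`.
#' @export
threshold_spectrum <- function(ps, threshold = "auto", auto_k = 1.0) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (identical(threshold, "auto")) {
    threshold <- min(max(auto_k * ps$mean_brightness, 0.05), 0.9)
  }
  assert_that(is.numeric(threshold) && length(threshold) == 1 &&
                threshold > 0 && threshold <= 1, "validation",
              "spectrum threshold must be in (0, 1] or \"auto\"")
  L <- log1p(Mod(ps$F))
  keep <- L >= threshold * max(L)
  keep[1, 1] <- TRUE  # DC
  out <- ps
  out$F[!keep] <- 0 + 0i
  out
}

# Feature angle (degrees, positive = rising toward the left with y
# pointing down) associated with each FFT bin. A feature at angle phi
# concentrates its spectral energy along phi + 90 in frequency space.
spectrum_feature_angles <- function(ps) {
  fy <- fft_freq_index(ps$nr) / ps$nr   # cycles per pixel, so angles
  fx <- fft_freq_index(ps$nc) / ps$nc   # are correct for non-square images
  ang <- atan2(outer(fy, rep(1, ps$nc)),
               outer(rep(1, ps$nr), fx)) * 180 / pi
  wrap_angle_180(ang - 90)
}

#' Directional (wedge) mask on a power spectrum
#'
#' Suppresses all frequency bins carrying image features oriented within
#' `suppress_halfwidth_deg` of `suppress_center_deg`. Angles are given
#' in FEATURE terms (the orientation of the image structure, not of its
#' spectral energy); the 90 degree rotation between a feature and its
#' spectrum is handled internally. The mask is symmetric about DC and
#' the DC bin itself is kept. Optional cosine tapering softens the wedge
#' edges to reduce ringing.
#'
#' @param ps a `power_spectrum`.
#' @param suppress_center_deg centre of the suppressed feature-angle wedge.
#' @param suppress_halfwidth_deg half-width of the wedge in (0, 90).
#' @param taper_deg width of an optional cosine taper beyond the hard
#'   edge (0 = hard-edged wedge).
#' @return a filtered `power_spectrum`.
#' @export
orientation_mask <- function(ps, suppress_center_deg,
                             suppress_halfwidth_deg, taper_deg = 0) {
  stopifnot(inherits(ps, "power_spectrum"))
  assert_that(suppress_halfwidth_deg > 0 && suppress_halfwidth_deg < 90,
              "validation", "mask halfwidth must be in (0, 90) degrees")
  d <- angdiff_180(spectrum_feature_angles(ps), suppress_center_deg)
  gain <- ifelse(d <= suppress_halfwidth_deg, 0,
                 ifelse(d >= suppress_halfwidth_deg + taper_deg, 1,
                        0.5 - 0.5 * cospi((d - suppress_halfwidth_deg) /
                                            max(taper_deg, 1e-9))))
  gain[1, 1] <- 1  # DC
  out <- ps
  out$F <- ps$F * gain
  out
}

# Robust noise-sd estimate from horizontal first differences.
estimate_noise_sd <- function(m) {
  d <- diff(t(m)) / sqrt(2)
  stats::mad(as.numeric(d))
}

#' Denoise an ultrasound image with a stage-specific preset
#'
#' Two presets mirror the two stages of the pipeline: the
#' `"aponeurosis"` preset (local contrast equalisation with CLAHE
#' followed by non-local-means at a heavier smoothing level) flattens
#' speckle aggressively before ridge detection, while the `"fascicle"`
#' preset (median filter followed by lighter non-local-means) preserves
#' the fine striations that carry the orientation signal.
#'
#' @param img numeric matrix in \[0,1\].
#' @param strength `"aponeurosis"` or `"fascicle"`.
#' @param nlm_patch,nlm_search non-local-means patch and search window
#'   widths (odd integers).
#' @return denoised matrix, same size.
#' @export
denoise <- function(img, strength = c("aponeurosis", "fascicle"),
                    nlm_patch = 5L, nlm_search = 11L) {
  strength <- match.arg(strength)
  m <- clamp01(as_raster(img))
  sd0 <- estimate_noise_sd(m)
  if (strength == "aponeurosis") {
    if (stats::sd(m) > 1e-12) {
      # CLAHE tiles must divide the image evenly; replicate-pad and crop back
      nr <- nrow(m); nc <- ncol(m)
      py <- (8 - nr %% 8) %% 8; px <- (8 - nc %% 8) %% 8
      mp <- pad_replicate(m, 0L, 0L)
      if (py > 0 || px > 0) mp <- mp[c(seq_len(nr), rep(nr, py)),
                                     c(seq_len(nc), rep(nc, px))]
      e <- EBImage::clahe(to_ebi(mp), nx = 8, ny = 8, limit = 1.2)
      m <- clamp01(from_ebi(e))[seq_len(nr), seq_len(nc)]
    }
    # CLAHE amplifies speckle along with contrast, so the smoothing
    # level is tied to the post-equalisation noise estimate
    h <- max(3 * estimate_noise_sd(m), 0.06)
  } else {
    m <- from_ebi(EBImage::medianFilter(to_ebi(m), size = 1))
    h <- max(0.6 * sd0, 0.01)
  }
  nlm_denoise_cpp(m, h = h, patch = as.integer(nlm_patch),
                  search = as.integer(nlm_search))
}
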