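# Bland-Altman agreement between two paired measurement series.

#' Bland-Altman agreement statistics
#'
#' Computes the bias (mean of the paired differences `a - b`) and the
#' 95% limits of agreement `bias +/- 1.96 * sd(d)` (sample SD, n - 1
#' denominator) between two measurement series of the same quantity.
#'
#' @param series_a,series_b paired measurement series (equal length,
#'   n >= 2).
#' @param plot draw the Bland-Altman plot (differences against pair
#'   means with bias and limit lines)?
#' @param ... graphics arguments passed to `plot()`.
#' @return object of class `sma_agreement` with fields `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(series_a, series_b, plot = FALSE, ...) {
  assert_that(length(series_a) == length(series_b), "validation",
              "bland_altman: series must have equal length")
  assert_that(length(series_a) >= 2, "validation",
              "bland_altman: need at least 2 pairs")
  d <- series_a - series_b
  bias <- mean(d)
  s <- stats::sd(d)
  res <- structure(list(bias = bias, loa_low = bias - 1.96 * s,
                        loa_high = bias + 1.96 * s, sd_diff = s,
                        n = length(d)),
                   class = "sma_agreement")
  if (plot) {
    mids <- (series_a + series_b) / 2
    graphics::plot(mids, d, xlab = "Mean of pair",
                   ylab = "Difference (a - b)", ...)
    graphics::abline(h = bias, lty = 1)
    graphics::abline(h = c(res$loa_low, res$loa_high), lty = 3)
  }
  res
}

#' @export
print.sma_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, 95%% limits [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
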