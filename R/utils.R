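#' Gaussian smoothing of a 1 ms trace
#'
#' Convolution with a Gaussian specified by its full width at half
#' maximum; edges are renormalized (the kernel mass falling outside the
#' trace is excluded) so constant traces are unchanged.
#'
#' @param x numeric vector on the 1 ms lattice.
#' @param fwhm_ms full width at half maximum (ms).
#' @param delta_ms sample spacing (ms).
#' @return smoothed numeric vector, same length.
#' @export
gaussian_smooth <- function(x, fwhm_ms, delta_ms = 1) {
  sigma <- fwhm_ms / (2 * sqrt(2 * log(2))) / delta_ms
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(xp, k, sides = 2)[half + seq_len(n)]
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- stats::filter(wp, k, sides = 2)[half + seq_len(n)]
  as.numeric(num / den)
}

#' Moving-average smoothing with shrinking edge windows
#'
#' Centered moving average of span `span` samples; near the edges the
#' window shrinks to the available samples (no zero padding), so
#' constant traces are preserved exactly.
#'
#' @param x numeric vector.
#' @param span window span in samples (ms on the 1 ms lattice).
#' @return smoothed numeric vector.
#' @export
moving_average <- function(x, span) {
  span <- as.integer(span)
  if (span <= 1) return(x)
  n <- length(x)
  lo <- (span - 1L) %/% 2L
  hi <- span - 1L - lo
  cs <- cumsum(c(0, x))
  i0 <- pmax(seq_len(n) - lo, 1L)
  i1 <- pmin(seq_len(n) + hi, n)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}
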