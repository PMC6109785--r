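#' @useDynLib fcmech, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm rbinom sd var cor fft pt pnorm qnorm
#' @importFrom utils combn
NULL

#' Derive a stage-local seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed plus a fixed stage counter, so stages are individually reproducible
#' and inserting a new stage does not shift the streams of the others.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
fanout_seed <- function(master, counter) {
  # splitmix-style mix, folded into the positive 31-bit range
  x <- (as.double(master) * 2654435761 + as.double(counter) * 40503 + 12345)
  as.integer(x %% 2147483647)
}

#' Spatial correlation between two maps over a mask
#'
#' @param a,b numeric arrays or vectors of equal length.
#' @param mask optional logical mask; defaults to all entries.
#' @return Pearson correlation of the masked values.
#' @export
spatial_cor <- function(a, b, mask = NULL) {
  a <- as.vector(a); b <- as.vector(b)
  if (!is.null(mask)) {
    m <- as.vector(mask)
    a <- a[m]; b <- b[m]
  }
  stats::cor(a, b)
}

#' Z-scale a vector to zero mean, unit variance
#' @param x numeric vector.
#' @return scaled vector; constant input is returned as all zeros.
#' @keywords internal
zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Fraction of spectral power inside a frequency band
#'
#' One-sided periodogram power of `x` integrated over `[f_lo, f_hi]`,
#' divided by total power above DC.
#'
#' @param x numeric time series.
#' @param tr sampling interval in seconds.
#' @param f_lo,f_hi band edges in Hz.
#' @return scalar in `[0, 1]`.
#' @export
band_power_ratio <- function(x, tr, f_lo = 0.01, f_hi = 0.1) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) / (n * tr)
  half <- freq <= 1 / (2 * tr) & freq > 0
  tot <- sum(p[half])
  if (tot == 0) return(0)
  inband <- half & freq >= f_lo & freq <= f_hi
  sum(p[inband]) / tot
}
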