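#' High-pass temporal filtering by discrete cosine drift removal
#'
#' Removes slow drifts by projecting out a discrete cosine basis containing
#' all frequencies below `1/cutoff_seconds` (the filter "equivalent to" a
#' given cutoff period), together with the constant term, so each voxel's
#' output has mean zero. Deterministic and phase-free.
#'
#' @param vol a [volume4d].
#' @param cutoff_seconds cutoff period in seconds (must exceed `2 * tr`).
#' @return filtered [volume4d].
#' @export
highpass_filter <- function(vol, cutoff_seconds = 150) {
  if (cutoff_seconds <= 2 * vol$tr)
    stop("cutoff_seconds must exceed twice the repetition time")
  m <- vol_matrix(vol)                      # T x voxels
  n_t <- nrow(m)
  dur <- n_t * vol$tr
  k_max <- floor(2 * dur / cutoff_seconds)  # DCT order k has frequency k/(2*dur)
  tt <- seq_len(n_t) - 0.5
  basis <- cbind(1, if (k_max >= 1)
    sapply(seq_len(k_max), function(k) cos(pi * k * tt / n_t)))
  basis <- qr.Q(qr(basis))
  resid <- m - basis %*% crossprod(basis, m)
  matrix_to_vol(resid, vol)
}

#' Spatial Gaussian smoothing
#'
#' Separable per-timepoint 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` in mm, converted to voxels via the
#' affine. Boundaries are handled by reflection, which preserves the
#' spatial sum. `fwhm_mm = 0` is the identity.
#'
#' @param vol a [volume4d].
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @return smoothed [volume4d].
#' @export
spatial_smooth <- function(vol, fwhm_mm = 5) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  A <- vol$affine[1:3, 1:3]
  if (max(abs(A - diag(diag(A)))) > 1e-8)
    stop("unsupported geometry: affine with shear/rotation is not supported")
  voxdim <- abs(diag(A))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxdim
  d <- dim(vol$data)
  out <- vol$data
  for (ax in 1:3) {
    C <- .gauss_conv_matrix(d[ax], sigma_vox[ax])
    out <- .apply_along(out, ax, C)
  }
  volume4d(out, affine = vol$affine, tr = vol$tr, mask = vol$mask)
}

# 1D Gaussian convolution matrix with reflective boundaries
.gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (off in (-r):r) {
      j <- i + off
      # reflect about the half-sample boundary
      while (j < 1 || j > n) {
        if (j < 1) j <- 1 - j
        if (j > n) j <- 2 * n + 1 - j
      }
      C[i, j] <- C[i, j] + k[off + r + 1]
    }
  }
  C
}

# multiply matrix C along axis `ax` of a 4D array
.apply_along <- function(arr, ax, C) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:4, ax))
  m <- matrix(aperm(arr, perm), d[ax])
  m <- C %*% m
  aperm(array(m, d[perm]), order(perm))
}

#' Variance-normalize voxel time series
#'
#' Scales each in-mask voxel's time series to unit sample variance;
#' all-zero (zero-variance) series are left untouched.
#'
#' @param vol a [volume4d].
#' @return normalized [volume4d].
#' @export
variance_normalize <- function(vol) {
  m <- vol_matrix(vol)
  s <- sqrt(matrixStats_colVars(t(m)))
  s[s == 0] <- 1
  matrix_to_vol(sweep(m, 2, s, "/"), vol)
}

#' Standard per-subject preprocessing
#'
#' High-pass filter, spatial smoothing and variance normalization, in that
#' order (filtering before smoothing keeps the temporal and spatial
#' operators independent; either order gives the same result as they act
#' on different dimensions).
#'
#' @param vol a [volume4d].
#' @param highpass_sec high-pass cutoff period (seconds); `NULL` skips.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 skips.
#' @param varnorm logical; variance-normalize after filtering.
#' @return preprocessed [volume4d].
#' @export
preprocess <- function(vol, highpass_sec = 150, fwhm_mm = 5, varnorm = TRUE) {
  if (!is.null(highpass_sec)) vol <- highpass_filter(vol, highpass_sec)
  if (fwhm_mm > 0) vol <- spatial_smooth(vol, fwhm_mm)
  if (varnorm) vol <- variance_normalize(vol)
  vol
}
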