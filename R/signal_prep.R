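#' Temporal band-pass filter
#'
#' Frequency-domain ideal filter: each in-mask voxel series is demeaned,
#' transformed with the FFT, bins whose frequency falls outside
#' `[low_hz, high_hz]` are zeroed (the DC bin always is), and the series is
#' transformed back. Stop-band attenuation is exact on the FFT grid; this
#' matches the analysis chain used by resting-state toolboxes and makes the
#' spectral examples exact. The default band is 0.01--0.08 Hz.
#'
#' @param series A [volume_series()].
#' @param low_hz,high_hz Passband edges in Hz; `high_hz` must not exceed the
#'   Nyquist frequency `1/(2 tr_s)`.
#' @return A filtered `volume_series` (mask and affine untouched).
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(series, "volume_series"))
  nyq <- 1 / (2 * series$tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyq + 1e-12) stop("high_hz exceeds the Nyquist frequency ", nyq)
  d <- dim(series$data)
  nt <- d[4]
  vox <- which(series$mask)
  Y <- t(matrix(series$data, prod(d[1:3]), nt)[vox, , drop = FALSE])
  Y <- sweep(Y, 2, colMeans(Y))
  f <- fft_freqs(nt, series$tr_s)
  keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12 & seq_len(nt) != 1L
  Fy <- stats::mvfft(Y)
  Fy[!keep, ] <- 0
  Yf <- Re(stats::mvfft(Fy, inverse = TRUE)) / nt
  out <- array(0, d)
  M <- matrix(out, prod(d[1:3]), nt)
  M[vox, ] <- t(Yf)
  series$data <- array(M, d)
  series
}

# two-sided frequency magnitude of each FFT bin, length n
fft_freqs <- function(n, tr_s) {
  j <- 0:(n - 1)
  pmin(j, n - j) / (n * tr_s)
}

#' Spatial Gaussian smoothing
#'
#' Convolves each time frame with an isotropic Gaussian kernel of the given
#' full width at half maximum, `sigma = fwhm / (2 sqrt(2 log 2))`, realized as
#' three separable zero-padded 1-D convolutions. `fwhm_mm = 0` is the
#' identity. No mask renormalization is applied.
#'
#' @param series A [volume_series()].
#' @param fwhm_mm Kernel FWHM in mm (6 mm is the conventional choice for
#'   2-mm resting-state grids).
#' @return A smoothed `volume_series` (mask and affine untouched).
#' @export
smooth_volume <- function(series, fwhm_mm = 6) {
  stopifnot(inherits(series, "volume_series"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(series)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_mm
  series$data <- smooth_array(series$data, sigma_vox)
  series
}

# separable zero-padded Gaussian convolution of a 3-D or 4-D array, sigma in voxels
smooth_array <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  k <- gaussian_kernel(sigma_vox)
  Cs <- lapply(d[1:3], conv_matrix, kernel = k)
  nd <- length(d)
  # axis 1
  arr <- array(Cs[[1]] %*% matrix(arr, d[1]), d)
  # axis 2
  perm <- if (nd == 4L) c(2, 1, 3, 4) else c(2, 1, 3)
  arr <- aperm(arr, perm)
  arr <- array(Cs[[2]] %*% matrix(arr, d[2]), dim(arr))
  arr <- aperm(arr, perm)
  # axis 3
  perm <- if (nd == 4L) c(3, 2, 1, 4) else c(3, 2, 1)
  arr <- aperm(arr, perm)
  arr <- array(Cs[[3]] %*% matrix(arr, d[3]), dim(arr))
  aperm(arr, perm)
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# n x n banded matrix realizing zero-padded 1-D convolution with kernel k
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    C[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  C
}

#' Remove per-voxel linear trends
#'
#' Least-squares removal of intercept and linear slope from every in-mask
#' voxel series; the output is orthogonal to the constant and linear
#' regressors. Standard before spectral estimation.
#'
#' @param series A [volume_series()].
#' @return A detrended `volume_series`.
#' @export
detrend <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  d <- dim(series$data)
  nt <- d[4]
  if (nt < 3L) stop("need at least 3 time points to detrend")
  vox <- which(series$mask)
  Y <- t(matrix(series$data, prod(d[1:3]), nt)[vox, , drop = FALSE])
  X <- cbind(1, seq_len(nt))
  Y <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  M <- matrix(array(0, d), prod(d[1:3]), nt)
  M[vox, ] <- t(Y)
  series$data <- array(M, d)
  series
}
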