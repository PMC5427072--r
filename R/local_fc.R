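#' Kendall's coefficient of concordance
#'
#' Concordance of K time series over n time points. Each series is converted
#' to ranks across time (mid-ranks on ties, no tie-correction factor, matching
#' the original regional-homogeneity formulation); with rank sums `R_i` at each
#' time point and mean rank sum `Rbar = K(n+1)/2`,
#' `W = (sum R_i^2 - n Rbar^2) / (K^2 (n^3 - n) / 12)`.
#' W is 1 when all series share one rank ordering and 0 under perfectly
#' balanced disagreement.
#'
#' @param series_matrix Numeric matrix, K series in rows, n time points in
#'   columns.
#' @return Concordance in `[0, 1]`.
#' @export
kcc <- function(series_matrix) {
  m <- as.matrix(series_matrix)
  K <- nrow(m)
  n <- ncol(m)
  if (K < 2L || n < 2L) stop("need K >= 2 series and n >= 2 time points")
  if (any(apply(m, 1, function(x) max(x) == min(x))))
    stop("constant series: ranking undefined")
  ranks <- t(apply(m, 1, rank))
  R_i <- colSums(ranks)
  rbar <- K * (n + 1) / 2
  (sum(R_i^2) - n * rbar^2) / (K^2 * (n^3 - n) / 12)
}

# neighbourhood offsets for 7 (faces), 19 (faces+edges), 27 (full cube)
neighborhood_offsets <- function(neighborhood) {
  if (!neighborhood %in% c(7L, 19L, 27L))
    stop("neighborhood must be one of 7, 19, 27")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(g))
  keep <- switch(as.character(neighborhood),
                 "7"  = m <= 1,
                 "19" = m <= 2,
                 "27" = m <= 3)
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' Regional homogeneity map
#'
#' Per-voxel Kendall's W of the voxel's (band-passed) time series with its
#' neighbours: 27-voxel cube by default, with the value assigned to the
#' central voxel. Neighbours outside the mask are dropped and K reduced
#' accordingly; voxels whose usable K falls below 2 are undefined and counted
#' in a warning.
#'
#' @param series A [volume_series()], normally band-pass filtered.
#' @param neighborhood Cluster size: 7 (faces), 19 (faces+edges) or 27 (full
#'   3x3x3 cube).
#' @return A `brain_map` of kind `"reho"`.
#' @export
reho_map <- function(series, neighborhood = 27L) {
  stopifnot(inherits(series, "volume_series"))
  offs <- neighborhood_offsets(as.integer(neighborhood))
  d <- dim(series$data)
  res <- .reho_kcc_cpp(as.numeric(series$data), as.integer(d),
                       as.logical(series$mask), offs)
  if (res$n_undefined > 0L)
    warning(res$n_undefined, " voxel(s) had usable K < 2 and are undefined")
  brain_map(array(res$values, d[1:3]), series$mask, series$affine,
            kind = "reho", voxel_mm = series$voxel_mm)
}

#' Spectral band pair for fALFF
#'
#' @param num_low,num_high Numerator (low-frequency) band edges in Hz.
#' @param den_low,den_high Denominator (full-range) band edges in Hz.
#' @return A `spectral_bands` list.
#' @export
spectral_bands <- function(num_low = 0.01, num_high = 0.08,
                          den_low = 0.01, den_high = 0.25) {
  if (!(num_low >= den_low && num_high <= den_high))
    stop("numerator band must lie within the denominator band")
  if (!(num_low < num_high && den_low < den_high))
    stop("band edges must be increasing")
  structure(list(num_low = num_low, num_high = num_high,
                 den_low = den_low, den_high = den_high),
            class = "spectral_bands")
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' Each in-mask voxel series (detrended but NOT band-pass filtered) is
#' FFT-transformed; the amplitude at each frequency is the square root of the
#' power spectrum. fALFF is the sum of amplitudes over the low-frequency band
#' (0.01--0.08 Hz) divided by the sum over the full range (0.01--0.25 Hz).
#' Frequency bins are half-open `[low, high)` on the FFT grid and the DC bin
#' is always excluded. Voxels with a zero denominator are undefined.
#'
#' @param series A detrended, unfiltered [volume_series()].
#' @param bands A [spectral_bands()] object.
#' @return A `brain_map` of kind `"falff"` with values in `[0, 1]`.
#' @export
falff_map <- function(series, bands = spectral_bands()) {
  stopifnot(inherits(series, "volume_series"), inherits(bands, "spectral_bands"))
  nyq <- 1 / (2 * series$tr_s)
  if (bands$den_high > nyq + 1e-12)
    stop("denominator band exceeds the Nyquist frequency ", nyq)
  d <- dim(series$data)
  nt <- d[4]
  vox <- which(series$mask)
  Y <- t(matrix(series$data, prod(d[1:3]), nt)[vox, , drop = FALSE])
  Y <- sweep(Y, 2, colMeans(Y))
  amp <- Mod(stats::mvfft(Y))
  half <- 2:(floor(nt / 2) + 1L)          # positive-frequency bins, DC excluded
  f <- (half - 1) / (nt * series$tr_s)
  num <- f >= bands$num_low & f < bands$num_high
  den <- f >= bands$den_low & f < bands$den_high
  num_amp <- colSums(amp[half[num], , drop = FALSE])
  den_amp <- colSums(amp[half[den], , drop = FALSE])
  vals <- ifelse(den_amp > 0, num_amp / den_amp, NA_real_)
  n_undef <- sum(is.na(vals))
  if (n_undef > 0L)
    warning(n_undef, " voxel(s) had zero spectral amplitude and are undefined")
  out <- array(NA_real_, d[1:3])
  out[vox] <- vals
  brain_map(out, series$mask, series$affine, kind = "falff",
            voxel_mm = series$voxel_mm)
}

#' Standardize a map by its within-mask mean
#'
#' Divides every value by the mean over defined in-mask voxels, so the
#' standardized map has mean 1 — the usual normalization applied to regional
#' homogeneity and fALFF maps before group-level correlation.
#'
#' @param map A `brain_map`.
#' @return The standardized `brain_map`.
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "brain_map"))
  mu <- mean(map$values[map$mask], na.rm = TRUE)
  if (!is.finite(mu) || mu <= 0) stop("within-mask mean must be positive")
  map$values <- map$values / mu
  map
}
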