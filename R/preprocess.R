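#' Construct a brain mask
#'
#' @param data Logical (or 0/1) 3D array matching a volume's spatial grid.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  data <- array(as.logical(data), dim = dim(data))
  if (!any(data)) stop("a brain mask needs at least one voxel")
  structure(list(data = data), class = "brain_mask")
}

#' @rdname brain_mask
#' @param grid Integer triple; `full_mask()` builds an all-TRUE mask.
#' @export
full_mask <- function(grid) {
  brain_mask(array(TRUE, dim = as.integer(grid)))
}

#' Frequency band specification
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`. The
#'   default 0.01-0.1 Hz is the conventional low-frequency fluctuation band.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz = 0.01, high_hz = 0.1) {
  stopifnot(low_hz > 0, high_hz > low_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

check_band <- function(band, tr_seconds) {
  nyquist <- 1 / (2 * tr_seconds)
  if (band$high_hz > nyquist + 1e-12)
    stop(sprintf("band high edge %.4g Hz exceeds the Nyquist frequency %.4g Hz",
                 band$high_hz, nyquist))
  invisible(nyquist)
}

# T x V matrix of the in-mask voxel time series (V = in-mask voxel count).
mask_series <- function(volume, mask) {
  d <- dim(volume$data)
  stopifnot(all(d[1:3] == dim(mask$data)))
  m <- as.vector(mask$data)
  t(matrix(volume$data, nrow = prod(d[1:3]), ncol = d[4])[m, , drop = FALSE])
}

# Inverse of mask_series: put a T x V matrix back; out-of-mask voxels zeroed.
series_to_volume <- function(series, volume, mask) {
  d <- dim(volume$data)
  flat <- matrix(0, nrow = prod(d[1:3]), ncol = d[4])
  flat[as.vector(mask$data), ] <- t(series)
  out <- volume
  out$data <- array(flat, dim = d)
  out
}

#' Remove a least-squares linear trend per voxel
#'
#' For each in-mask voxel the best-fit line (intercept + slope * t) is
#' subtracted from the time series; out-of-mask voxels are zeroed.
#'
#' @param volume A [bold_volume()] with T >= 3.
#' @param mask A [brain_mask()] (default: full grid).
#' @return A detrended [bold_volume()].
#' @export
linear_detrend <- function(volume, mask = full_mask(dim(volume$data)[1:3])) {
  nt <- dim(volume$data)[4]
  if (nt < 3) stop("detrending needs at least 3 timepoints")
  y <- mask_series(volume, mask)
  x <- cbind(1, seq_len(nt))
  beta <- solve(crossprod(x), crossprod(x, y))
  series_to_volume(y - x %*% beta, volume, mask)
}

# Indices (1-based, into the length-T DFT) of bins with low <= f <= high,
# up to a 1e-12 tie tolerance at the edges. DC (f = 0) is never in band.
band_bins <- function(n_timepoints, tr_seconds, band) {
  f <- (seq_len(n_timepoints) - 1) / (n_timepoints * tr_seconds)
  pos <- f <= 1 / (2 * tr_seconds) + 1e-12 & seq_len(n_timepoints) > 1
  which(pos & f >= band$low_hz - 1e-12 & f <= band$high_hz + 1e-12)
}

#' Ideal bandpass filter
#'
#' Rectangular frequency-domain filter: discrete-Fourier bins with
#' `low_hz <= f <= high_hz` are retained, all others (including DC) are
#' zeroed, and the series is inverse-transformed. Applied per in-mask voxel;
#' out-of-mask voxels are zeroed.
#'
#' @param volume A [bold_volume()].
#' @param band A [band_spec()] valid for the volume's TR.
#' @param mask A [brain_mask()].
#' @return A filtered [bold_volume()].
#' @export
bandpass_filter <- function(volume, band = band_spec(),
                            mask = full_mask(dim(volume$data)[1:3])) {
  check_band(band, volume$tr_seconds)
  nt <- dim(volume$data)[4]
  keep_pos <- band_bins(nt, volume$tr_seconds, band)
  keep <- rep(FALSE, nt)
  keep[keep_pos] <- TRUE
  # retain the conjugate-symmetric partners so the inverse transform is real
  partners <- ((nt - (keep_pos - 1)) %% nt) + 1
  keep[partners] <- TRUE
  y <- mask_series(volume, mask)
  yf <- stats::mvfft(y)
  yf[!keep, ] <- 0
  out <- Re(stats::mvfft(yf, inverse = TRUE)) / nt
  series_to_volume(out, volume, mask)
}

# 1D Gaussian kernel sampled at integer offsets, sd in voxels.
gauss_kernel_1d <- function(sd_vox) {
  r <- max(1L, ceiling(4 * sd_vox))
  k <- exp(-((-r:r)^2) / (2 * sd_vox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a centred 1D kernel, zero padding.
convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, dim = d)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    dst_idx <- which(ok)
    src_idx <- src[ok]
    if (axis == 1L) out[dst_idx, , ] <- out[dst_idx, , ] + kernel[j] * a[src_idx, , ]
    else if (axis == 2L) out[, dst_idx, ] <- out[, dst_idx, ] + kernel[j] * a[, src_idx, ]
    else out[, , dst_idx] <- out[, , dst_idx] + kernel[j] * a[, , src_idx]
  }
  out
}

#' Mask-renormalised Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution with per-axis standard deviation (in
#' voxels) `fwhm_mm / (2 sqrt(2 log 2)) / voxel_size_mm[axis]`. Out-of-mask
#' voxels are excluded from both input and output: the masked map is
#' convolved and divided by the convolved mask, which preserves constants
#' exactly and avoids dimming at mask borders.
#'
#' @param map3d Numeric 3D array.
#' @param fwhm_mm Positive kernel full width at half maximum, in mm.
#' @param voxel_size_mm Numeric triple of voxel edge lengths in mm.
#' @param mask A [brain_mask()].
#' @return A smoothed 3D array (zero outside the mask).
#' @export
gaussian_smooth <- function(map3d, fwhm_mm, voxel_size_mm = c(3, 3, 3),
                            mask = full_mask(dim(map3d))) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  stopifnot(all(dim(map3d) == dim(mask$data)))
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  m <- mask$data
  num <- map3d * m
  den <- m * 1
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sd_vox[ax])
    num <- convolve_axis(num, k, ax)
    den <- convolve_axis(den, k, ax)
  }
  out <- array(0, dim = dim(map3d))
  out[m] <- num[m] / den[m]
  out
}
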