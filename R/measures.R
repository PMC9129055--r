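#' Construct an activity map
#'
#' Container for one subject's 3D voxel-wise measure map.
#'
#' @param data Numeric 3D array.
#' @param measure One of `"alff"`, `"falff"`, `"reho"`, `"vmhc"`.
#' @param mask The [brain_mask()] the map was computed over.
#' @param standardized Logical; has the map been z-scored over the mask?
#' @param flagged Optional logical 3D array marking voxels whose value was
#'   set by a degenerate-input rule (isolated voxels, unpaired mirrors,
#'   zero-variance series).
#' @return An object of class `activity_map`.
#' @export
activity_map <- function(data, measure, mask, standardized = FALSE,
                         flagged = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            all(dim(data) == dim(mask$data)))
  measure <- match.arg(measure, c("alff", "falff", "reho", "vmhc"))
  if (!all(is.finite(data[mask$data]))) stop("in-mask map values must be finite")
  structure(list(data = data, measure = measure, mask = mask,
                 standardized = standardized,
                 flagged = flagged %||% array(FALSE, dim = dim(data))),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<activity_map> %s, %d x %d x %d, %d in-mask voxels%s\n",
              toupper(x$measure), d[1], d[2], d[3], sum(x$mask$data),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

# One-sided amplitude spectrum per in-mask voxel: bins 2|X(f)|/T for
# positive frequencies f <= Nyquist. Returns list(amp = bins x V, f = freqs).
amplitude_spectrum <- function(volume, mask) {
  y <- mask_series(volume, mask)
  nt <- nrow(y)
  yf <- stats::mvfft(y)
  f_all <- (seq_len(nt) - 1) / (nt * volume$tr_seconds)
  pos <- which(seq_len(nt) > 1 & f_all <= 1 / (2 * volume$tr_seconds) + 1e-12)
  list(amp = 2 * Mod(yf[pos, , drop = FALSE]) / nt, f = f_all[pos])
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per in-mask voxel: the mean one-sided amplitude-spectrum value
#' `2|X(f)|/T` over discrete-Fourier bins with frequency inside the band
#' (default 0.01-0.1 Hz). Expects a detrended (not bandpassed) volume.
#' With `type = "power"` the mean of `(2|X(f)|/T)^2` is used instead.
#'
#' @param volume A detrended [bold_volume()], T >= 16.
#' @param mask A [brain_mask()].
#' @param band A [band_spec()].
#' @param type `"amplitude"` (default) or `"power"`.
#' @return An [activity_map()] with measure `"alff"`.
#' @export
compute_alff <- function(volume, mask = full_mask(dim(volume$data)[1:3]),
                         band = band_spec(), type = c("amplitude", "power")) {
  type <- match.arg(type)
  nt <- dim(volume$data)[4]
  if (nt < 16) stop("ALFF needs at least 16 timepoints")
  check_band(band, volume$tr_seconds)
  sp <- amplitude_spectrum(volume, mask)
  inb <- sp$f >= band$low_hz - 1e-12 & sp$f <= band$high_hz + 1e-12
  if (!any(inb))
    stop("no frequency bins fall inside the band; series too short for the TR")
  amp <- if (type == "power") sp$amp^2 else sp$amp
  vals <- colMeans(amp[inb, , drop = FALSE])
  out <- array(0, dim = dim(mask$data))
  out[mask$data] <- vals
  activity_map(out, "alff", mask)
}

#' Fractional ALFF (fALFF)
#'
#' Per in-mask voxel: the sum of amplitude-spectrum values over in-band bins
#' divided by the sum over all positive-frequency bins up to the Nyquist
#' frequency (0.25 Hz at TR = 2 s). A 0/0 ratio is defined as 0.
#'
#' @inheritParams compute_alff
#' @return An [activity_map()] with measure `"falff"`, values in `[0, 1]`.
#' @export
compute_falff <- function(volume, mask = full_mask(dim(volume$data)[1:3]),
                          band = band_spec(), type = c("amplitude", "power")) {
  type <- match.arg(type)
  nt <- dim(volume$data)[4]
  if (nt < 16) stop("fALFF needs at least 16 timepoints")
  check_band(band, volume$tr_seconds)
  sp <- amplitude_spectrum(volume, mask)
  inb <- sp$f >= band$low_hz - 1e-12 & sp$f <= band$high_hz + 1e-12
  if (!any(inb))
    stop("no frequency bins fall inside the band; series too short for the TR")
  amp <- if (type == "power") sp$amp^2 else sp$amp
  num <- colSums(amp[inb, , drop = FALSE])
  den <- colSums(amp)
  vals <- ifelse(den > 0, num / den, 0)
  out <- array(0, dim = dim(mask$data))
  out[mask$data] <- vals
  activity_map(out, "falff", mask)
}

# Kendall's coefficient of concordance for a T x K matrix of series
# (columns are judges ranked over time). Average ranks for ties, no tie
# correction. W = 12 sum_t (R_t - Rbar)^2 / (K^2 (T^3 - T)).
kendall_w <- function(series) {
  nt <- nrow(series)
  k <- ncol(series)
  ranks <- apply(series, 2, rank)
  r_t <- rowSums(ranks)
  rbar <- k * (nt + 1) / 2
  12 * sum((r_t - rbar)^2) / (k^2 * (nt^3 - nt))
}

# List of in-mask linear indices of the 3x3x3 cube around each in-mask voxel.
neighbourhood_index <- function(mask) {
  d <- dim(mask$data)
  inmask <- which(mask$data)
  coord <- arrayInd(inmask, d)
  # map from linear voxel index to column in the in-mask series matrix
  col_of <- integer(prod(d))
  col_of[inmask] <- seq_along(inmask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lapply(seq_along(inmask), function(i) {
    nb <- sweep(offs, 2, coord[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    cols <- col_of[lin]
    cols[cols > 0L]
  })
}

#' Regional homogeneity (ReHo)
#'
#' Per in-mask voxel: Kendall's coefficient of concordance W among the time
#' series of the up-to-27 in-mask voxels of the 3x3x3 cube centred on it.
#' Ranks use the average-rank convention for ties and no tie correction.
#' Mask-edge voxels use their available K < 27 neighbours; isolated voxels
#' (K < 2) get value 0 and are flagged. Expects a bandpassed volume.
#'
#' @param volume A filtered [bold_volume()], T >= 4.
#' @param mask A [brain_mask()].
#' @return An [activity_map()] with measure `"reho"`, values in `[0, 1]`.
#' @export
compute_reho <- function(volume, mask = full_mask(dim(volume$data)[1:3])) {
  nt <- dim(volume$data)[4]
  if (nt < 4) stop("ReHo needs at least 4 timepoints")
  y <- mask_series(volume, mask)
  ranks <- apply(y, 2, rank)
  nbrs <- neighbourhood_index(mask)
  k_vec <- lengths(nbrs)
  rbar_unit <- (nt + 1) / 2
  denom_t <- nt^3 - nt
  vals <- vapply(seq_along(nbrs), function(i) {
    k <- k_vec[i]
    if (k < 2) return(0)
    r_t <- rowSums(ranks[, nbrs[[i]], drop = FALSE])
    12 * sum((r_t - k * rbar_unit)^2) / (k^2 * denom_t)
  }, numeric(1))
  out <- array(0, dim = dim(mask$data))
  out[mask$data] <- vals
  flagged <- array(FALSE, dim = dim(mask$data))
  flagged[mask$data] <- k_vec < 2
  activity_map(out, "reho", mask, flagged = flagged)
}

#' Voxel-mirrored homotopic connectivity (VMHC)
#'
#' The mirror of voxel (x, y, z) is (X + 1 - x, y, z) with the first grid
#' axis taken as left-right. For each in-mask voxel whose mirror is in-mask
#' and distinct, the value is the Fisher z-transform `atanh(r)` of the
#' Pearson correlation between the two series, with r clipped to
#' `[-1 + 1e-7, 1 - 1e-7]`. Self-mirrored (midline) or unpaired voxels and
#' zero-variance series give value 0 and are flagged. Expects a bandpassed
#' volume; assumes the grid is already left-right symmetric.
#'
#' @param volume A filtered [bold_volume()].
#' @param mask A [brain_mask()].
#' @return An [activity_map()] with measure `"vmhc"` (Fisher-z values).
#' @export
compute_vmhc <- function(volume, mask = full_mask(dim(volume$data)[1:3])) {
  d <- dim(volume$data)
  y <- mask_series(volume, mask)
  inmask <- which(mask$data)
  coord <- arrayInd(inmask, d[1:3])
  col_of <- integer(prod(d[1:3]))
  col_of[inmask] <- seq_along(inmask)
  mir <- cbind(d[1] + 1L - coord[, 1], coord[, 2], coord[, 3])
  mir_lin <- mir[, 1] + d[1] * (mir[, 2] - 1) + d[1] * d[2] * (mir[, 3] - 1)
  mir_col <- col_of[mir_lin]
  self <- mir_lin == inmask
  sds <- apply(y, 2, stats::sd)
  vals <- numeric(length(inmask))
  flagged <- logical(length(inmask))
  pair_ok <- mir_col > 0L & !self
  degenerate <- pair_ok & (sds < .Machine$double.eps |
                             sds[pmax(mir_col, 1L)] < .Machine$double.eps)
  usable <- pair_ok & !degenerate
  if (any(usable)) {
    idx <- which(usable)
    r <- vapply(idx, function(i) stats::cor(y[, i], y[, mir_col[i]]), numeric(1))
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
    vals[idx] <- atanh(r)
  }
  flagged[!usable] <- TRUE
  out <- array(0, dim = dim(mask$data))
  out[mask$data] <- vals
  fl <- array(FALSE, dim = dim(mask$data))
  fl[mask$data] <- flagged
  activity_map(out, "vmhc", mask, flagged = fl)
}

#' Z-score an activity map over its mask
#'
#' In-mask voxels are standardised to mean 0 and population (1/N) standard
#' deviation 1; out-of-mask voxels stay 0.
#'
#' @param map An [activity_map()] with >= 2 in-mask voxels and nonzero
#'   in-mask variance.
#' @return The standardised [activity_map()].
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "activity_map"))
  v <- map$data[map$mask$data]
  if (length(v) < 2) stop("standardisation needs at least 2 in-mask voxels")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv < .Machine$double.eps) stop("zero variance across the mask")
  out <- map
  out$data[map$mask$data] <- (v - mu) / sdv
  out$standardized <- TRUE
  out
}

#' Extract one measure map from a raw volume
#'
#' Runs the per-subject chain for a single measure: linear detrend for all
#' measures; ALFF/fALFF are computed on the detrended series (bandpassing
#' first would fix fALFF at 1), ReHo and VMHC on the detrended-and-bandpassed
#' series. The map is then z-scored over the mask, and the ALFF, fALFF and
#' ReHo maps are smoothed with a Gaussian kernel (default FWHM 4 mm); VMHC
#' is not re-smoothed.
#'
#' @param volume A raw [bold_volume()].
#' @param measure One of `"alff"`, `"falff"`, `"reho"`, `"vmhc"`.
#' @param mask A [brain_mask()].
#' @param band A [band_spec()].
#' @param fwhm_mm Smoothing kernel FWHM in mm; `NA` disables smoothing.
#' @return An [activity_map()].
#' @export
extract_measure <- function(volume, measure, mask = full_mask(dim(volume$data)[1:3]),
                            band = band_spec(), fwhm_mm = 4) {
  measure <- match.arg(measure, c("alff", "falff", "reho", "vmhc"))
  det <- linear_detrend(volume, mask)
  map <- switch(measure,
    alff = compute_alff(det, mask, band),
    falff = compute_falff(det, mask, band),
    reho = compute_reho(bandpass_filter(det, band, mask), mask),
    vmhc = compute_vmhc(bandpass_filter(det, band, mask), mask)
  )
  map <- standardize_map(map)
  if (!is.na(fwhm_mm) && measure != "vmhc") {
    map$data <- gaussian_smooth(map$data, fwhm_mm, volume$voxel_size_mm, mask)
  }
  map
}

#' Extract measure maps for a whole cohort
#'
#' @param cohort A cohort tibble (columns `subject_id`, `label`, `volume`).
#' @param measures Character vector of measures to extract.
#' @inheritParams extract_measure
#' @return A tibble with one row per (subject, measure): columns
#'   `subject_id`, `label`, `measure`, `map` (list of [activity_map()]).
#' @export
cohort_activity_maps <- function(cohort, measures = c("alff", "falff", "reho", "vmhc"),
                                 mask = NULL, band = band_spec(), fwhm_mm = 4) {
  stopifnot(nrow(cohort) >= 1, length(measures) >= 1)
  mask <- mask %||% full_mask(dim(cohort$volume[[1]]$data)[1:3])
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    maps <- purrr::map(measures, function(m)
      extract_measure(cohort$volume[[i]], m, mask, band, fwhm_mm))
    tibble::tibble(subject_id = cohort$subject_id[i],
                   label = cohort$label[i],
                   measure = measures, map = maps)
  })
  dplyr::bind_rows(rows)
}
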