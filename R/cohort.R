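#' Construct a 4D BOLD volume
#'
#' Lightweight container for one subject's blood-oxygenation-level-dependent
#' (BOLD) time series on a regular voxel grid.
#'
#' @param data Numeric 4D array, X x Y x Z x T.
#' @param voxel_size_mm Positive numeric triple, voxel edge lengths in mm.
#' @param tr_seconds Positive scalar, repetition time (sampling interval) in
#'   seconds.
#'
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, voxel_size_mm = c(3, 3, 3), tr_seconds = 2) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[4] < 2L) stop("a BOLD volume needs at least 2 timepoints")
  if (!all(is.finite(data))) stop("BOLD values must all be finite")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(tr_seconds) == 1L, tr_seconds > 0)
  structure(
    list(data = data,
         voxel_size_mm = as.numeric(voxel_size_mm),
         tr_seconds = as.numeric(tr_seconds)),
    class = "bold_volume"
  )
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_volume> %d x %d x %d voxels, %d timepoints, TR %g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr_seconds,
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' @export
dim.bold_volume <- function(x) dim(x$data)

#' Describe a planted group effect
#'
#' An effect region plants a group difference in one of the three measure
#' families the pipeline is sensitive to: low-frequency amplitude (`"alff"`),
#' local temporal coherence (`"reho"`), or mirrored inter-hemispheric
#' correlation (`"vmhc"`).
#'
#' @param kind One of `"alff"`, `"reho"`, `"vmhc"`.
#' @param voxels Integer matrix with 3 columns (x, y, z grid coordinates,
#'   1-based) listing the voxels carrying the effect. For `"vmhc"` the set
#'   must be closed under the left-right mirror map `x -> X + 1 - x`.
#' @param effect_size For `"alff"`: multiplicative amplitude factor (>= 0) of
#'   an in-band oscillation. For `"reho"`/`"vmhc"`: mixing weight in `[0, 1]`
#'   of a shared latent time series.
#' @param applies_to `"patients"` or `"controls"`.
#'
#' @return An object of class `effect_region`.
#' @export
effect_region <- function(kind = c("alff", "reho", "vmhc"), voxels,
                          effect_size, applies_to = c("patients", "controls")) {
  kind <- match.arg(kind)
  applies_to <- match.arg(applies_to)
  voxels <- as.matrix(voxels)
  stopifnot(ncol(voxels) == 3L, nrow(voxels) >= 1L)
  storage.mode(voxels) <- "integer"
  stopifnot(length(effect_size) == 1L, is.finite(effect_size))
  if (kind %in% c("reho", "vmhc") && (effect_size < 0 || effect_size > 1))
    stop("mixing-weight effect sizes must lie in [0, 1]")
  if (kind == "alff" && effect_size < 0)
    stop("amplitude effect sizes must be non-negative")
  structure(list(kind = kind, voxels = voxels,
                 effect_size = as.numeric(effect_size),
                 applies_to = applies_to),
            class = "effect_region")
}

#' Specify a synthetic two-group cohort
#'
#' Defines the study conditions for a synthetic resting-state cohort: grid and
#' sampling geometry, group sizes, baseline noise level and the planted group
#' effects. Defaults give a desk-scale cohort (12 x 14 x 12 grid, T = 120,
#' TR = 2 s, 10 + 10 subjects) that runs through the full pipeline in well
#' under two minutes.
#'
#' @param n_patients,n_controls Group sizes (>= 1).
#' @param grid Integer triple of grid dimensions (each >= 4).
#' @param n_timepoints Number of timepoints T (>= 16).
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param effect_regions List of [effect_region()] objects.
#' @param baseline_noise_sd Standard deviation of the baseline Gaussian noise
#'   carried by every voxel (the intensity unit of the simulation).
#' @param seed Integer master seed; subject seeds are derived as
#'   `seed * 1e6 + subject_index`.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10, n_controls = 10,
                        grid = c(12, 14, 12), n_timepoints = 120,
                        tr_seconds = 2, voxel_size_mm = c(3, 3, 3),
                        effect_regions = list(), baseline_noise_sd = 1,
                        seed = 1) {
  stopifnot(n_patients >= 1, n_controls >= 1,
            length(grid) == 3L, all(grid >= 4),
            n_timepoints >= 16, tr_seconds > 0,
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            baseline_noise_sd >= 0, is.finite(baseline_noise_sd),
            length(seed) == 1L)
  grid <- as.integer(grid)
  for (reg in effect_regions) {
    if (!inherits(reg, "effect_region")) stop("effect_regions must be a list of effect_region objects")
    v <- reg$voxels
    if (any(v < 1L) || any(v[, 1] > grid[1]) || any(v[, 2] > grid[2]) ||
        any(v[, 3] > grid[3]))
      stop("effect region lies outside the grid")
    if (reg$kind == "vmhc") {
      mirrored <- cbind(grid[1] + 1L - v[, 1], v[, 2], v[, 3])
      key <- function(m) paste(m[, 1], m[, 2], m[, 3])
      if (!all(key(mirrored) %in% key(v)))
        stop("a vmhc effect region must be closed under the x-mirror map")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 grid = grid, n_timepoints = as.integer(n_timepoints),
                 tr_seconds = as.numeric(tr_seconds),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 effect_regions = effect_regions,
                 baseline_noise_sd = as.numeric(baseline_noise_sd),
                 seed = as.numeric(seed)),
            class = "cohort_spec")
}

# Sum of n_sin unit sinusoids with frequencies uniform in [0.01, 0.1] Hz and
# random phases, scaled to unit standard deviation. Guarantees in-band
# spectral energy so amplitude/coherence effects are well defined.
low_freq_latent <- function(n_timepoints, tr_seconds, n_sin = 5) {
  t_sec <- (seq_len(n_timepoints) - 1) * tr_seconds
  f <- stats::runif(n_sin, 0.01, 0.1)
  phi <- stats::runif(n_sin, 0, 2 * pi)
  s <- rowSums(vapply(seq_len(n_sin),
                      function(i) sin(2 * pi * f[i] * t_sec + phi[i]),
                      numeric(n_timepoints)))
  s_sd <- stats::sd(s)
  if (s_sd < .Machine$double.eps) return(rep(0, n_timepoints))
  s / s_sd
}

#' Generate one synthetic subject
#'
#' Every voxel carries independent Gaussian noise plus a common linear drift.
#' Voxels inside an effect region whose `applies_to` matches `group`
#' additionally carry the planted signal: a band-limited 0.01-0.1 Hz
#' oscillation scaled by the effect size (`"alff"`), or a shared latent
#' low-frequency series mixed in with the effect-size weight (`"reho"`,
#' mixed across the region; `"vmhc"`, mixed identically into each voxel and
#' its left-right mirror). Mixing uses weights `(sqrt(1 - e^2), e)` so the
#' marginal voxel variance is preserved.
#'
#' @param spec A [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed Integer seed; the same seed reproduces the subject
#'   bit for bit.
#'
#' @return A [bold_volume()].
#' @export
generate_subject <- function(spec, group, subject_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("patient", "control"))
    stop("group must be 'patient' or 'control'")
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  nt <- spec$n_timepoints
  set.seed(as.integer(subject_seed %% 2147483647))

  dat <- array(stats::rnorm(nx * ny * nz * nt, sd = spec$baseline_noise_sd),
               dim = c(nx, ny, nz, nt))
  # common slow drift, removed downstream by the linear detrend
  drift_slope <- stats::rnorm(1, sd = 0.01)
  drift <- drift_slope * (seq_len(nt) - (nt + 1) / 2) * spec$tr_seconds
  dat <- dat + rep(drift, each = nx * ny * nz)

  grp <- if (group == "patient") "patients" else "controls"
  for (reg in spec$effect_regions) {
    if (reg$applies_to != grp) next
    v <- reg$voxels
    e <- reg$effect_size
    idx4 <- function(vox) cbind(vox[rep(seq_len(nrow(vox)), nt), , drop = FALSE],
                                rep(seq_len(nt), each = nrow(vox)))
    if (reg$kind == "alff") {
      osc <- low_freq_latent(nt, spec$tr_seconds) * e * spec$baseline_noise_sd
      ii <- idx4(v)
      dat[ii] <- dat[ii] + rep(osc, each = nrow(v))
    } else if (reg$kind == "reho") {
      latent <- low_freq_latent(nt, spec$tr_seconds) * spec$baseline_noise_sd
      ii <- idx4(v)
      dat[ii] <- sqrt(1 - e^2) * dat[ii] + e * rep(latent, each = nrow(v))
    } else { # vmhc: same latent into each voxel and its mirror (set is closed)
      key <- paste(v[, 1], v[, 2], v[, 3])
      mirror_x <- nx + 1L - v[, 1]
      done <- character(0)
      for (r in seq_len(nrow(v))) {
        if (key[r] %in% done) next
        mkey <- paste(mirror_x[r], v[r, 2], v[r, 3])
        latent <- low_freq_latent(nt, spec$tr_seconds) * spec$baseline_noise_sd
        pair <- unique(rbind(v[r, , drop = FALSE],
                             c(mirror_x[r], v[r, 2], v[r, 3])))
        ii <- cbind(pair[rep(seq_len(nrow(pair)), nt), , drop = FALSE],
                    rep(seq_len(nt), each = nrow(pair)))
        dat[ii] <- sqrt(1 - e^2) * dat[ii] + e * rep(latent, each = nrow(pair))
        done <- c(done, key[r], mkey)
      }
    }
  }
  bold_volume(dat, spec$voxel_size_mm, spec$tr_seconds)
}

#' Generate a labelled synthetic cohort
#'
#' Patients come first, then controls; subject seeds are
#' `spec$seed * 1e6 + subject_index` so any subject can be regenerated alone.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `label` (factor,
#'   patient/control) and `volume` (list of [bold_volume()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients + spec$n_controls
  labels <- factor(rep(c("patient", "control"),
                       c(spec$n_patients, spec$n_controls)),
                   levels = c("patient", "control"))
  vols <- purrr::map(seq_len(n), function(i) {
    generate_subject(spec, as.character(labels[i]), spec$seed * 1e6 + i)
  })
  tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    label = labels,
    volume = vols
  )
}

#' Add Rician noise to a volume
#'
#' Magnitude-MRI noise model: each value v becomes
#' `sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)` independent.
#' Output values are non-negative by construction; `sigma = 0` returns the
#' input unchanged. Sigma is expressed in the intensity units of the volume
#' (for synthetic cohorts, units of the baseline noise sd).
#'
#' @param volume A [bold_volume()].
#' @param sigma Non-negative noise level.
#' @param noise_seed Integer seed; the corruption is deterministic given it.
#' @return A [bold_volume()] with corrupted values.
#' @export
add_rician_noise <- function(volume, sigma, noise_seed) {
  stopifnot(inherits(volume, "bold_volume"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(volume)
  set.seed(as.integer(noise_seed %% 2147483647))
  n <- length(volume$data)
  n1 <- stats::rnorm(n, sd = sigma)
  n2 <- stats::rnorm(n, sd = sigma)
  out <- volume
  out$data <- array(sqrt((volume$data + n1)^2 + n2^2), dim = dim(volume$data))
  out
}

#' Write / read a cohort as NIfTI-1 files
#'
#' One 4D NIfTI file per subject (`<subject_id>.nii.gz`) plus a
#' `labels.csv` table with columns `subject_id,label`.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    v <- cohort$volume[[i]]
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- c(v$voxel_size_mm, v$tr_seconds)
    RNifti::writeNifti(img, file.path(dir, paste0(cohort$subject_id[i], ".nii.gz")))
  }
  utils::write.csv(data.frame(subject_id = cohort$subject_id,
                              label = as.character(cohort$label)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  vols <- purrr::map(lab$subject_id, function(id) {
    img <- RNifti::readNifti(file.path(dir, paste0(id, ".nii.gz")))
    pd <- RNifti::pixdim(img)
    bold_volume(array(as.numeric(img), dim = dim(img)),
                voxel_size_mm = pd[1:3],
                tr_seconds = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1)
  })
  tibble::tibble(subject_id = lab$subject_id,
                 label = factor(lab$label, levels = c("patient", "control")),
                 volume = vols)
}
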