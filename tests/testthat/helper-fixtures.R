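# Shared fixture builders. Everything is generated in code with fixed seeds.

# Volume holding an arbitrary 4D array with unit-variance defaults.
toy_volume <- function(data, tr = 2, voxel = c(3, 3, 3)) {
  bold_volume(data, voxel_size_mm = voxel, tr_seconds = tr)
}

# White-noise volume on a small grid.
noise_volume <- function(grid = c(6, 6, 6), nt = 64, tr = 2, seed = 1) {
  set.seed(seed)
  toy_volume(array(rnorm(prod(grid) * nt), dim = c(grid, nt)), tr = tr)
}

# Volume where every voxel carries the same given time series.
series_volume <- function(series, grid = c(4, 4, 4), tr = 2) {
  nt <- length(series)
  toy_volume(array(rep(series, each = prod(grid)), dim = c(grid, nt)), tr = tr)
}

# A labelled feature matrix with planted mean shifts on chosen columns.
planted_fm <- function(n_per_class = 15, p = 8, informative = 1,
                       shift = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  for (j in informative) x[seq_len(n_per_class), j] <- x[seq_len(n_per_class), j] + shift
  feature_matrix(x, rep(c("patient", "control"), each = n_per_class))
}

# Train/validation pair where three complementary features are each needed:
# each informative feature separates a different third of the patients, so
# any support-recovery method must keep all three.
complementary_pair <- function(shift = 6, seed = 1, n_train = 15,
                               n_valid = 200, p = 8, feats = c(1, 4, 7)) {
  set.seed(seed)
  gen <- function(n) {
    x <- matrix(rnorm(2 * n * p), 2 * n, p)
    thirds <- split(seq_len(n), cut(seq_len(n), length(feats), labels = FALSE))
    for (b in seq_along(feats))
      x[thirds[[b]], feats[b]] <- x[thirds[[b]], feats[b]] + shift
    feature_matrix(x, rep(c("patient", "control"), each = n))
  }
  list(train = gen(n_train), valid = gen(n_valid))
}

# Exhaustive best-k-subset oracle: train a linear SVM on the training half
# restricted to each C(p, k) subset and score it on the large validation
# half; return the best subset. Independent of the rankers it checks.
best_subset_oracle <- function(pair, k = 3) {
  p <- ncol(pair$train$values)
  combos <- utils::combn(p, k)
  accs <- apply(combos, 2, function(feats) {
    m <- train_linear(rsfusion:::fm_subset(pair$train, NULL, feats), C = 10)
    mean(predict(m, rsfusion:::fm_subset(pair$valid, NULL, feats))$label ==
           pair$valid$labels)
  })
  combos[, which.max(accs)]
}

# Desk-scale cohort spec with strong planted effects in all three families.
effect_cohort_spec <- function(n_per_group = 10, seed = 11,
                               alff_size = 3, reho_size = 0.8, vmhc_size = 0.8) {
  grid <- c(12, 12, 12)
  regions <- list(
    effect_region("alff", as.matrix(expand.grid(2:4, 2:4, 2:4)),
                  alff_size, "patients"),
    effect_region("reho", as.matrix(expand.grid(8:10, 2:4, 8:10)),
                  reho_size, "patients"),
    effect_region("vmhc", as.matrix(expand.grid(c(2, 11), 6:8, 6:8)),
                  vmhc_size, "patients")
  )
  cohort_spec(n_patients = n_per_group, n_controls = n_per_group,
              grid = grid, n_timepoints = 100,
              effect_regions = regions, seed = seed)
}

# Zero-effect (null) cohort spec.
null_cohort_spec <- function(n_per_group = 10, seed = 21) {
  cohort_spec(n_patients = n_per_group, n_controls = n_per_group,
              grid = c(8, 8, 8), n_timepoints = 64, seed = seed)
}

# Brute-force Kendall's W oracle: explicit rank sums, average ranks for ties.
kendall_w_oracle <- function(series) {
  nt <- nrow(series); k <- ncol(series)
  ranks <- apply(series, 2, rank)
  r_t <- rowSums(ranks)
  12 * sum((r_t - mean(r_t))^2) / (k^2 * (nt^3 - nt))
}
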