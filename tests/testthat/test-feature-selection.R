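test_that("feature matrices count voxels and preserve provenance blocks", {
  # full standard-space grid: one measure -> 271633 features
  big_mask <- full_mask(c(61, 73, 61))
  expect_equal(sum(big_mask$data), 271633)

  # small end-to-end construction
  spec <- cohort_spec(n_patients = 2, n_controls = 2, grid = c(4, 4, 4),
                      n_timepoints = 32, seed = 3)
  coh <- generate_cohort(spec)
  m <- array(FALSE, dim = c(4, 4, 4)); m[1:10] <- TRUE
  mask <- brain_mask(m)
  maps <- cohort_activity_maps(coh, c("alff", "reho"), mask, fwhm_mm = NA)
  fm <- maps_to_feature_matrix(maps, mask)
  expect_equal(dim(fm), c(4L, 20L))
  expect_equal(fm$provenance$measure, rep(c("alff", "reho"), each = 10))
  expect_error(maps_to_feature_matrix(maps, mask, measures = character(0)),
               "at least one")
  # matrix values are exactly the in-mask map voxels, in mask order
  expect_equal(fm$values[1, 1:10], maps$map[[1]]$data[m])
})

test_that("FSV concentrates weight on the separating feature", {
  hits <- vapply(1:20, function(r) {
    fm <- planted_fm(n_per_class = 20, p = 2, informative = 1, shift = 2,
                     seed = 700 + r)
    s <- with(rank_fsv(fm), score[order(feature)])
    s[1] > 10 * s[2]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("FSV's top-3 matches the exhaustive best 3-subset on planted problems", {
  # three complementary informative features, each carried by a different
  # third of the patients, so a minimal separating support needs all three
  hits <- vapply(1:20, function(r) {
    pair <- complementary_pair(shift = 6, seed = 900 + r)
    top3 <- sort(rank_fsv(pair$train)$feature[1:3])
    setequal(top3, sort(best_subset_oracle(pair, 3)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("FSV degenerates gracefully and sparsifies with lambda", {
  # tiny lambda: still a valid permutation with index tie-breaks
  fm <- planted_fm(n_per_class = 10, p = 5, informative = 1, seed = 31)
  rf <- rank_fsv(fm, fsv_params(lambda = 1e-9))
  expect_setequal(rf$feature, 1:5)

  # support size is non-increasing in lambda
  fm2 <- planted_fm(n_per_class = 15, p = 10, informative = c(1, 2, 3),
                    shift = 1.5, seed = 32)
  support <- vapply(c(0.1, 0.5, 0.9), function(lam) {
    s <- rank_fsv(fm2, fsv_params(lambda = lam))$score
    sum(s > 0.01 * max(s))
  }, numeric(1))
  expect_true(all(diff(support) <= 0))
})

test_that("L0-norm rescaling finds planted and duplicated features", {
  hits <- vapply(1:20, function(r) {
    fm <- planted_fm(n_per_class = 15, p = 10, informative = 1, shift = 2,
                     seed = 1100 + r)
    rank_l0(fm)$feature[1] == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # duplicated informative column: the pair occupies the top two ranks
  set.seed(33)
  x <- matrix(rnorm(30 * 5), 30, 5)
  x[1:15, 1] <- x[1:15, 1] + 3
  x[, 2] <- x[, 1]
  fm <- feature_matrix(x, rep(c("patient", "control"), each = 15))
  expect_setequal(rank_l0(fm)$feature[1:2], c(1, 2))

  # max_rounds = 1 equals |w| of a single trained classifier
  fm3 <- planted_fm(n_per_class = 10, p = 6, informative = 2, seed = 34)
  r1 <- rank_l0(fm3, max_rounds = 1)
  std <- rsfusion:::standardize_columns(fm3$values)$x
  w <- abs(rsfusion:::svm_weights(std, fm3$labels, 10)$w)
  w <- w / max(w)
  expect_equal(with(r1, score[order(feature)]), unname(w), tolerance = 1e-10)
})

test_that("Relief weights follow the nearest hit/miss update rule", {
  # constant feature -> weight 0
  fm <- planted_fm(n_per_class = 5, p = 3, informative = 1, seed = 35)
  fm$values[, 3] <- 7
  expect_equal(with(rank_relief(fm), score[order(feature)])[3], 0)

  # 1D perfectly separated at 0 and 1 -> weight +1
  x <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  fm1 <- feature_matrix(x, rep(c("patient", "control"), each = 3))
  expect_equal(rank_relief(fm1)$score[1], 1)

  # permutation null: mean weight of the informative feature ~ 0
  set.seed(36)
  base <- planted_fm(n_per_class = 8, p = 2, informative = 1, shift = 3, seed = 37)
  w_perm <- replicate(200, {
    fmp <- feature_matrix(base$values, sample(as.character(base$labels)))
    with(rank_relief(fmp), score[order(feature)])[1]
  })
  expect_lt(abs(mean(w_perm)), 3 * sd(w_perm) / sqrt(200))

  # a subject whose class has a single member is skipped with a warning
  x2 <- rbind(base$values, base$values[1, ])
  expect_warning(
    rank_relief(feature_matrix(x2[c(1, 9:16, 17), ],
                               c("patient", rep("control", 8), "patient")[c(1, 2:10)])),
    NA)
})

test_that("Wilcoxon ranking reproduces exact enumeration", {
  # {1,2,3} vs {4,5,6}: minimal rank sum, exact two-sided p = 2/20
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  fm <- feature_matrix(x, rep(c("patient", "control"), each = 3))
  rf <- rank_wilcoxon(fm)
  expect_equal(rf$p_value[1], 0.1, tolerance = 1e-12)
  # R's own exact test agrees
  expect_equal(rf$p_value[1],
               wilcox.test(1:3, 4:6, exact = TRUE)$p.value, tolerance = 1e-12)

  # constant feature -> p = 1
  xc <- cbind(c(1, 2, 3, 4, 5, 6), rep(2, 6))
  fmc <- feature_matrix(xc, rep(c("patient", "control"), each = 3))
  expect_equal(rank_wilcoxon(fmc)$p_value[2], 1)

  # fully separated feature outranks an overlapping one
  set.seed(38)
  xs <- cbind(c(1:5, 6:10), c(rnorm(10)))
  fms <- feature_matrix(xs, rep(c("patient", "control"), each = 5))
  expect_equal(rank_wilcoxon(fms)$feature[1], 1)

  # normal approximation branch agrees with R for larger tied samples
  set.seed(39)
  xl <- matrix(round(rnorm(60), 1), ncol = 1)
  fml <- feature_matrix(xl, rep(c("patient", "control"), each = 30))
  p_ref <- wilcox.test(xl[1:30], xl[31:60], exact = FALSE, correct = TRUE)$p.value
  expect_equal(rank_wilcoxon(fml)$p_value[1], p_ref, tolerance = 1e-10)
})

test_that("all rankers return permutations invariant to feature reordering", {
  fm <- planted_fm(n_per_class = 8, p = 7, informative = c(2, 5), seed = 40)
  set.seed(41)
  perm <- sample(7)
  fm_perm <- rsfusion:::fm_subset(fm, NULL, perm)
  for (method in c("fsv", "l0", "relief", "wilcoxon")) {
    rf <- rank_features(fm, method)
    expect_setequal(rf$feature, 1:7)
    rf_perm <- rank_features(fm_perm, method)
    # mapping permuted ranks back must give the same score per feature
    orig_scores <- with(rf, score[order(feature)])
    back_scores <- with(rf_perm, score[order(feature)])[order(perm)]
    expect_equal(back_scores, orig_scores, tolerance = 1e-8)
  }
})

test_that("sequential forward selection picks the smallest argmax", {
  mk <- function(profile) {
    ranked <- rsfusion:::ranked_features(seq_along(profile), rev(seq_along(profile)), "wilcoxon")
    sequential_forward_select(ranked, function(k) profile[k], length(profile))
  }
  expect_equal(mk(c(0.6, 0.7, 0.9, 0.85))$k, 3)
  expect_equal(mk(c(0.8, 0.8, 0.8))$k, 1)
  expect_equal(mk(c(0.5, 0.6, 0.7, 0.8))$k, 4)
  ranked <- rsfusion:::ranked_features(1:3, 3:1, "wilcoxon")
  expect_error(sequential_forward_select(ranked, function(k) 1, 0), "at least 1")
  expect_error(sequential_forward_select(ranked, function(k) 1, 4), "exceeds")
})

test_that("rankers recover planted voxels from a synthetic cohort", {
  spec <- effect_cohort_spec(n_per_group = 8, seed = 43)
  coh <- generate_cohort(spec)
  mask <- full_mask(c(12, 12, 12))
  maps <- cohort_activity_maps(coh, "alff", mask)
  fm <- maps_to_feature_matrix(maps, mask)
  planted <- which(mask$data &
    array(seq_len(1728) %in%
            (function(v) v[, 1] + 12 * (v[, 2] - 1) + 144 * (v[, 3] - 1))(
              as.matrix(expand.grid(2:4, 2:4, 2:4))),
          dim = c(12, 12, 12)))
  # smoothing spreads the effect; demand most of the top 20 lie in or next to
  # the planted block
  near <- as.matrix(expand.grid(1:5, 1:5, 1:5))
  near_idx <- near[, 1] + 12 * (near[, 2] - 1) + 144 * (near[, 3] - 1)
  # per-method thresholds: the univariate and relief rankers localise the
  # block sharply; the multivariate L0 rescaling spreads a little more
  expect_gte(sum(rank_wilcoxon(fm)$feature[1:20] %in% near_idx), 15)
  expect_gte(sum(rank_relief(fm)$feature[1:20] %in% near_idx), 15)
  expect_gte(sum(rank_l0(fm)$feature[1:20] %in% near_idx), 12)
  # FSV recovers complementary planted supports at its working scale
  pair <- complementary_pair(shift = 6, seed = 44)
  expect_gte(sum(rank_fsv(pair$train)$feature[1:3] %in% c(1, 4, 7)), 2)
})
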