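#' Classification metrics from confusion counts
#'
#' Patients are the positive class: accuracy = (TP + TN) / N,
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). A metric with
#' a zero denominator is undefined and reported as `NA`, never as 0.
#'
#' @param tp,fp,tn,fn Non-negative counts, or a data frame with columns
#'   `TP`, `FP`, `TN`, `FN` as first argument (counts are summed).
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    fr <- tp
    tp <- sum(fr$TP); fp <- sum(fr$FP); tn <- sum(fr$TN); fn <- sum(fr$FN)
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("no observations")
  tibble::tibble(
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble with `estimate`, `low`, `high`.
#' @export
wilson_interval <- function(successes, n, conf = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p_hat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(estimate = p_hat,
                 low = max(0, centre - half),
                 high = min(1, centre + half))
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(labels, k, fold_seed) {
  set.seed(as.integer(fold_seed %% 2147483647))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k && length(idx) < 1)
      stop("class too small for stratified folds")
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Empirical ROC curve from decision values
#'
#' Sweeps the classification threshold over the observed decision values
#' (patient iff `d >= threshold`). The curve starts at (0, 0), ends at
#' (1, 1), and both coordinates are non-decreasing.
#'
#' @param decision_values Numeric vector of classifier decision values.
#' @param labels True labels (`"patient"` positive).
#' @return A tibble of class `roc_curve` with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(decision_values, labels) {
  stopifnot(length(decision_values) == length(labels))
  labels <- factor(as.character(labels), levels = c("patient", "control"))
  n_pos <- sum(labels == "patient")
  n_neg <- sum(labels == "control")
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes")
  thr <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred_pos <- decision_values >= th
    c(fpr = sum(pred_pos & labels == "control") / n_neg,
      tpr = sum(pred_pos & labels == "patient") / n_pos)
  }, numeric(2)))
  structure(tibble::tibble(fpr = pts[, 1], tpr = pts[, 2]),
            class = c("roc_curve", class(tibble::tibble())))
}

#' Vertically averaged ROC curve
#'
#' At each false-positive rate of the grid, every curve's true-positive rate
#' is obtained by linear interpolation and the values are averaged across
#' curves; the AUC of the averaged curve is computed by the trapezoid rule.
#'
#' @param curves List of [roc_curve()] tibbles (at least one).
#' @param fpr_grid Ascending false-positive-rate grid in `[0, 1]`
#'   (default 101 evenly spaced points).
#' @return A list with `curve` (tibble `fpr`, `tpr`) and `auc`.
#' @export
roc_vertical_average <- function(curves, fpr_grid = seq(0, 1, length.out = 101)) {
  stopifnot(length(curves) >= 1, !is.unsorted(fpr_grid),
            all(fpr_grid >= 0), all(fpr_grid <= 1))
  tpr_mat <- vapply(curves, function(cv) {
    if (nrow(cv) == 0) stop("empty ROC curve")
    # step interpolation with upper corners: the tpr achievable at each
    # fpr, so a single curve's trapezoid AUC equals its empirical AUC
    stats::approx(cv$fpr, cv$tpr, xout = fpr_grid, ties = max, rule = 2,
                  method = "constant", f = 0)$y
  }, numeric(length(fpr_grid)))
  tpr_mean <- rowMeans(as.matrix(tpr_mat))
  auc <- sum(diff(fpr_grid) * (utils::head(tpr_mean, -1) + utils::tail(tpr_mean, -1)) / 2)
  list(curve = structure(tibble::tibble(fpr = fpr_grid, tpr = tpr_mean),
                         class = c("roc_curve", class(tibble::tibble()))),
       auc = auc)
}

# Train-and-evaluate for one outer fold: rank on the training subjects,
# choose k by inner stratified cross-validation (sequential forward
# selection), train the final model on all training subjects with the top-k
# features. Test labels are used only for the confusion counts.
run_outer_fold <- function(x, train_idx, test_idx, ranker, k_max, C,
                           n_inner, inner_seed, ranker_args = list()) {
  xtr <- fm_subset(x, train_idx)
  ranked <- do.call(rank_features, c(list(xtr, method = ranker), ranker_args))
  k_max <- min(k_max, ncol(xtr$values), 200L)
  inner_fold <- stratified_folds(xtr$labels, n_inner, inner_seed)
  evaluator <- function(k) {
    feats <- ranked$feature[seq_len(k)]
    accs <- vapply(seq_len(n_inner), function(f) {
      tr <- which(inner_fold != f); va <- which(inner_fold == f)
      if (length(va) == 0 || nlevels(droplevels(xtr$labels[tr])) < 2) return(NA_real_)
      m <- train_linear(fm_subset(xtr, tr, feats), C)
      pred <- predict(m, fm_subset(xtr, va, feats))
      mean(pred$label == xtr$labels[va])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }
  sel <- sequential_forward_select(ranked, evaluator, k_max)
  feats <- ranked$feature[seq_len(sel$k)]
  model <- train_linear(fm_subset(xtr, NULL, feats), C)
  xte <- fm_subset(x, test_idx, feats)
  pred <- predict(model, xte)
  list(selected_k = sel$k, features = feats,
       selected_features = x$provenance[feats, , drop = FALSE],
       model = model, prediction = pred,
       truth = x$labels[test_idx])
}

fold_counts <- function(pred_label, truth) {
  c(TP = sum(pred_label == "patient" & truth == "patient"),
    FP = sum(pred_label == "patient" & truth == "control"),
    TN = sum(pred_label == "control" & truth == "control"),
    FN = sum(pred_label == "control" & truth == "patient"))
}

#' Nested cross-validation with optional fusion
#'
#' Runs repeated stratified nested cross-validation (default 5 repetitions
#' of an outer 10-fold loop). Per outer fold, the feature ranking and all
#' standardisation statistics are computed on the training subjects only;
#' an inner stratified cross-validation drives sequential forward selection
#' of the feature count; the final model is trained on all non-test subjects
#' and applied once to the held-out fold. No test subject influences
#' selection or standardisation.
#'
#' Schemes: `"single"` takes one feature matrix; `"feature"` fuses a list of
#' matrices by column concatenation before selection; `"decision"` runs the
#' full selection-and-training chain per matrix (sharing the fold
#' assignment) and fuses the three predicted labels by majority vote, with
#' the mean decision value used for ROC analysis.
#'
#' @param x A `feature_matrix`, or a list of them for the fusion schemes
#'   (exactly 3 for `"decision"`).
#' @param scheme `"single"`, `"decision"` or `"feature"`.
#' @param n_rep,n_outer,n_inner Repetition and fold counts.
#' @param ranker Feature-ranking method (see [rank_features()]).
#' @param k_max Largest feature count tried by forward selection
#'   (capped at 200 and at the feature count).
#' @param C Soft-margin penalty.
#' @param seed Master seed; all fold assignments derive from it.
#' @param ranker_args Extra arguments for the ranker.
#' @return A `cv_report`: list with `folds` (tibble per repetition x fold:
#'   counts, selected k, list-columns of selected features and test
#'   predictions), `roc` (vertically averaged ROC and AUC), `config`.
#' @export
nested_cv <- function(x, scheme = c("single", "decision", "feature"),
                      n_rep = 5, n_outer = 10, n_inner = 10,
                      ranker = "wilcoxon", k_max = 20, C = 10, seed = 1,
                      ranker_args = list()) {
  scheme <- match.arg(scheme)
  if (scheme == "single") {
    stopifnot(inherits(x, "feature_matrix"))
    mats <- list(x)
  } else if (scheme == "feature") {
    stopifnot(is.list(x), length(x) >= 2)
    mats <- list(feature_fusion(x))
  } else {
    stopifnot(is.list(x), length(x) == 3)
    mats <- x
  }
  labels <- mats[[1]]$labels
  if (min(table(labels)) < n_outer)
    stop("smallest class is too small for the outer fold count")
  rows <- list()
  fold_curves <- list()
  for (rep_i in seq_len(n_rep)) {
    outer_fold <- stratified_folds(labels, n_outer, seed * 1000 + rep_i)
    for (f in seq_len(n_outer)) {
      test_idx <- which(outer_fold == f)
      train_idx <- which(outer_fold != f)
      if (length(test_idx) == 0) next
      frs <- lapply(mats, function(m)
        run_outer_fold(m, train_idx, test_idx, ranker, k_max, C, n_inner,
                       inner_seed = seed * 100000 + rep_i * 100 + f,
                       ranker_args = ranker_args))
      truth <- labels[test_idx]
      if (scheme == "decision") {
        vote_mat <- do.call(cbind, lapply(frs, function(fr) as.character(fr$prediction$label)))
        lab <- majority_vote(vote_mat)
        dval <- rowMeans(do.call(cbind, lapply(frs, function(fr) fr$prediction$decision_value)))
      } else {
        lab <- frs[[1]]$prediction$label
        dval <- frs[[1]]$prediction$decision_value
      }
      cnt <- fold_counts(lab, truth)
      rows[[length(rows) + 1]] <- tibble::tibble(
        repetition = rep_i, fold = f,
        TP = cnt["TP"], FP = cnt["FP"], TN = cnt["TN"], FN = cnt["FN"],
        selected_k = list(vapply(frs, `[[`, numeric(1), "selected_k")),
        selected_features = list(lapply(frs, `[[`, "selected_features")),
        predictions = list(tibble::tibble(
          subject_id = mats[[1]]$subject_id[test_idx],
          truth = truth, label = lab, decision_value = dval))
      )
      if (length(unique(truth)) == 2) {
        fold_curves[[length(fold_curves) + 1]] <- roc_curve(dval, truth)
      }
    }
  }
  folds <- dplyr::bind_rows(rows)
  roc <- if (length(fold_curves) > 0) roc_vertical_average(fold_curves) else NULL
  structure(list(folds = folds, roc = roc,
                 config = list(scheme = scheme, n_rep = n_rep,
                               n_outer = n_outer, n_inner = n_inner,
                               ranker = ranker, k_max = k_max, C = C,
                               seed = seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cv_report> %s scheme, %d reps x %d outer folds\n",
              x$config$scheme, x$config$n_rep, x$config$n_outer))
  cat(sprintf("  accuracy %.3f [Wilson 95%%: %.3f, %.3f], sensitivity %.3f, specificity %.3f%s\n",
              g$accuracy, g$accuracy_low, g$accuracy_high,
              g$sensitivity, g$specificity,
              if (!is.null(x$roc)) sprintf(", AUC %.3f", g$auc) else ""))
  invisible(x)
}

#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::bind_cols(
    x$folds[, c("repetition", "fold", "TP", "FP", "TN", "FN")],
    purrr::map_dfr(seq_len(nrow(x$folds)), function(i)
      compute_metrics(x$folds$TP[i], x$folds$FP[i], x$folds$TN[i], x$folds$FN[i]))
  )
}

#' Aggregate a cross-validation report
#'
#' Metrics are computed on pooled confusion counts within each repetition
#' and averaged across repetitions; `accuracy_sd` is the across-repetition
#' standard deviation, and the Wilson 95% interval is computed on the
#' pooled counts over all repetitions.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  per_rep <- dplyr::group_by(x$folds, .data$repetition)
  per_rep <- dplyr::summarise(per_rep,
                              TP = sum(.data$TP), FP = sum(.data$FP),
                              TN = sum(.data$TN), FN = sum(.data$FN))
  met <- purrr::map_dfr(seq_len(nrow(per_rep)), function(i)
    compute_metrics(per_rep$TP[i], per_rep$FP[i], per_rep$TN[i], per_rep$FN[i]))
  tot_succ <- sum(x$folds$TP) + sum(x$folds$TN)
  tot_n <- sum(x$folds$TP + x$folds$FP + x$folds$TN + x$folds$FN)
  wi <- wilson_interval(tot_succ, tot_n)
  tibble::tibble(
    accuracy = mean(met$accuracy),
    accuracy_sd = stats::sd(met$accuracy),
    sensitivity = mean(met$sensitivity, na.rm = TRUE),
    specificity = mean(met$specificity, na.rm = TRUE),
    accuracy_low = wi$low, accuracy_high = wi$high,
    auc = if (!is.null(x$roc)) x$roc$auc else NA_real_
  )
}

#' Paired 5x2-cv t-test between two classifiers
#'
#' Five repetitions of stratified 2-fold cross-validation are run with both
#' classifiers sharing every fold. With \eqn{p_i^{(j)}} the accuracy
#' difference (A minus B) on fold j of repetition i,
#' \eqn{\bar p_i} the repetition mean and
#' \eqn{s_i^2 = (p_i^{(1)}-\bar p_i)^2 + (p_i^{(2)}-\bar p_i)^2},
#' the statistic is
#' \deqn{t = p_1^{(1)} \Big/ \sqrt{\tfrac{1}{5}\sum_{i=1}^5 s_i^2},}
#' compared against the two-sided 5% critical value of a t distribution
#' with 5 degrees of freedom (2.57). If every \eqn{s_i^2} is zero the
#' statistic is 0 when \eqn{p_1^{(1)} = 0} and infinite (flagged, rejected)
#' otherwise.
#'
#' @param classifier_a,classifier_b Functions `(train, test) -> factor of
#'   predicted labels`, where both arguments are `feature_matrix` objects;
#'   see [svm_pipeline_classifier()].
#' @param x A `feature_matrix` (or list of two, one per classifier, sharing
#'   subjects — e.g. different measures for the same cohort).
#' @param seed Master seed for the five fold assignments.
#' @return A list with `t`, `reject`, `t_critical`, `diffs` (5 x 2 matrix)
#'   and `degenerate` (TRUE when all variances were zero).
#' @export
five_by_two_test <- function(classifier_a, classifier_b, x, seed = 1) {
  xs <- if (inherits(x, "feature_matrix")) list(x, x) else x
  stopifnot(length(xs) == 2,
            identical(xs[[1]]$subject_id, xs[[2]]$subject_id))
  labels <- xs[[1]]$labels
  diffs <- matrix(NA_real_, 5, 2)
  for (i in 1:5) {
    fold <- stratified_folds(labels, 2, seed * 1000 + i)
    for (j in 1:2) {
      tr <- which(fold != j); te <- which(fold == j)
      acc <- vapply(1:2, function(c_i) {
        clf <- if (c_i == 1) classifier_a else classifier_b
        pred <- clf(fm_subset(xs[[c_i]], tr), fm_subset(xs[[c_i]], te))
        mean(as.character(pred) == as.character(labels[te]))
      }, numeric(1))
      diffs[i, j] <- acc[1] - acc[2]
    }
  }
  p_bar <- rowMeans(diffs)
  s2 <- (diffs[, 1] - p_bar)^2 + (diffs[, 2] - p_bar)^2
  t_critical <- stats::qt(0.975, df = 5)
  degenerate <- all(s2 == 0)
  if (degenerate) {
    t_stat <- if (diffs[1, 1] == 0) 0 else Inf * sign(diffs[1, 1])
  } else {
    t_stat <- diffs[1, 1] / sqrt(mean(s2))
  }
  list(t = t_stat, reject = is.infinite(t_stat) || abs(t_stat) > t_critical,
       t_critical = t_critical, diffs = diffs, degenerate = degenerate)
}

#' Build a rank-select-train classifier for [five_by_two_test()]
#'
#' Ranks features on the training subjects, keeps the top `k`, trains a
#' soft-margin linear model and predicts the test subjects.
#'
#' @param ranker Ranking method (see [rank_features()]).
#' @param k Number of top-ranked features to keep.
#' @param C Soft-margin penalty.
#' @param ranker_args Extra arguments for the ranker.
#' @return A function `(train, test) -> factor of predicted labels`.
#' @export
svm_pipeline_classifier <- function(ranker = "wilcoxon", k = 10, C = 10,
                                    ranker_args = list()) {
  force(ranker); force(k); force(C); force(ranker_args)
  function(train, test) {
    ranked <- do.call(rank_features, c(list(train, method = ranker), ranker_args))
    feats <- ranked$feature[seq_len(min(k, nrow(ranked)))]
    model <- train_linear(fm_subset(train, NULL, feats), C)
    predict(model, fm_subset(test, NULL, feats))$label
  }
}

# 26-connectivity connected components of a logical 3D array.
connected_components_26 <- function(mask3d) {
  d <- dim(mask3d)
  comp <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  next_id <- 0L
  todo <- which(mask3d)
  for (start in todo) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    comp[start] <- next_id
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      lin <- lin[mask3d[lin] & comp[lin] == 0L]
      comp[lin] <- next_id
      queue <- c(queue, lin)
    }
  }
  comp
}

#' Voxel-wise discriminative mapping with FDR control
#'
#' Per in-mask voxel, a pooled-variance two-sample t statistic (patients
#' minus controls) with its two-sided p-value; Benjamini-Hochberg step-up
#' control of the false discovery rate at level `q` gives the significance
#' mask. Clusters are 26-connectivity components of the significance mask
#' and each cluster's peak is its voxel of maximum |t|. Voxels with zero
#' within-group variance get p = 1 and are flagged.
#'
#' @param maps Tibble with columns `label` and `map` (one [activity_map()]
#'   per subject, single measure), e.g. one measure's rows from
#'   [cohort_activity_maps()].
#' @param q FDR level (default 0.05).
#' @param min_abs_t Optional pre-threshold: voxels must additionally have
#'   `|t| >= min_abs_t` to enter the significance mask (off by default).
#' @return A list with `t_map` (3D array), `p_map`, `significant` (logical
#'   3D array), `peaks` (tibble: `cluster`, `x`, `y`, `z`, `peak_t`,
#'   `n_voxels`) and `flagged`.
#' @export
discriminative_map <- function(maps, q = 0.05, min_abs_t = NULL) {
  stopifnot(nrow(maps) >= 4)
  mask <- maps$map[[1]]$mask
  inmask <- which(mask$data)
  vals <- vapply(maps$map, function(m) m$data[inmask], numeric(length(inmask)))
  is_pat <- maps$label == "patient"
  n1 <- sum(is_pat); n2 <- sum(!is_pat)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  m1 <- rowMeans(vals[, is_pat, drop = FALSE])
  m2 <- rowMeans(vals[, !is_pat, drop = FALSE])
  v1 <- apply(vals[, is_pat, drop = FALSE], 1, stats::var)
  v2 <- apply(vals[, !is_pat, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  flagged <- se < .Machine$double.eps
  tstat <- ifelse(flagged, 0, (m1 - m2) / ifelse(flagged, 1, se))
  pval <- ifelse(flagged, 1,
                 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2))
  p_adj <- stats::p.adjust(pval, method = "BH")
  sig <- p_adj <= q
  if (!is.null(min_abs_t)) sig <- sig & abs(tstat) >= min_abs_t
  t_map <- array(0, dim = dim(mask$data)); t_map[inmask] <- tstat
  p_map <- array(1, dim = dim(mask$data)); p_map[inmask] <- pval
  sig_map <- array(FALSE, dim = dim(mask$data)); sig_map[inmask] <- sig
  fl_map <- array(FALSE, dim = dim(mask$data)); fl_map[inmask] <- flagged
  comp <- connected_components_26(sig_map)
  peaks <- if (max(comp) > 0) {
    purrr::map_dfr(seq_len(max(comp)), function(ci) {
      vox <- which(comp == ci)
      peak <- vox[which.max(abs(t_map[vox]))]
      cc <- arrayInd(peak, dim(mask$data))
      tibble::tibble(cluster = ci, x = cc[1], y = cc[2], z = cc[3],
                     peak_t = t_map[peak], n_voxels = length(vox))
    })
  } else {
    tibble::tibble(cluster = integer(), x = integer(), y = integer(),
                   z = integer(), peak_t = numeric(), n_voxels = integer())
  }
  list(t_map = t_map, p_map = p_map, significant = sig_map, peaks = peaks,
       flagged = fl_map)
}

#' Rician-noise robustness protocol
#'
#' Stratified k-fold protocol: per fold, features are extracted from clean
#' volumes, ranked on the training subjects, the feature count chosen by
#' inner validation, and a linear model trained — once, on clean data only.
#' Then for each noise level sigma, only the held-out test volumes are
#' corrupted with Rician noise, their features re-extracted, and the stored
#' selection and model re-applied. The sigma = 0 row runs the identical
#' code path with no corruption and therefore reproduces the noiseless
#' evaluation exactly.
#'
#' @param cohort Cohort tibble (`subject_id`, `label`, `volume`).
#' @param measures Measures to extract and fuse (column concatenation).
#' @param sigmas Non-negative noise levels, in units of the volume
#'   intensities (for synthetic cohorts, the baseline noise sd).
#' @param mask A [brain_mask()].
#' @param seed Master seed (folds and noise streams derive from it).
#' @param n_folds,n_inner Outer and inner fold counts.
#' @param ranker,k_max,C Selection and classifier settings as in
#'   [nested_cv()].
#' @param band,fwhm_mm Extraction settings as in [extract_measure()].
#' @return A tibble with one row per sigma: `sigma`, `accuracy`,
#'   `sensitivity`, `specificity`, plus the per-fold trained models in
#'   attribute `"models"`.
#' @export
rician_robustness <- function(cohort, measures = c("alff", "reho", "vmhc"),
                              sigmas = c(0, 1, 2), mask = NULL, seed = 1,
                              n_folds = 5, n_inner = 5, ranker = "wilcoxon",
                              k_max = 15, C = 10, band = band_spec(),
                              fwhm_mm = 4) {
  if (any(sigmas < 0)) stop("sigma must be non-negative")
  mask <- mask %||% full_mask(dim(cohort$volume[[1]]$data)[1:3])
  clean_maps <- cohort_activity_maps(cohort, measures, mask, band, fwhm_mm)
  x <- maps_to_feature_matrix(clean_maps, mask, measures)
  labels <- x$labels
  fold <- stratified_folds(labels, n_folds, seed * 1000 + 1)
  trained <- lapply(seq_len(n_folds), function(f) {
    run_outer_fold(x, which(fold != f), which(fold == f), ranker, k_max, C,
                   n_inner, inner_seed = seed * 10000 + f)
  })
  extract_subject_features <- function(volume) {
    maps <- lapply(measures, function(m)
      extract_measure(volume, m, mask, band, fwhm_mm))
    unlist(lapply(maps, function(mp) mp$data[which(mask$data)]))
  }
  rows <- purrr::map_dfr(seq_along(sigmas), function(si) {
    sigma <- sigmas[si]
    counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (f in seq_len(n_folds)) {
      te <- which(fold == f)
      if (sigma == 0) {
        rowsv <- x$values[te, , drop = FALSE]
      } else {
        rowsv <- t(vapply(te, function(s) {
          noisy <- add_rician_noise(cohort$volume[[s]], sigma,
                                    noise_seed = seed * 100000 + si * 1000 + s)
          extract_subject_features(noisy)
        }, numeric(ncol(x$values))))
      }
      feats <- trained[[f]]$features
      pred <- predict(trained[[f]]$model, rowsv[, feats, drop = FALSE])
      counts <- counts + fold_counts(pred$label, labels[te])
    }
    dplyr::bind_cols(tibble::tibble(sigma = sigma),
                     compute_metrics(counts["TP"], counts["FP"],
                                     counts["TN"], counts["FN"]))
  })
  attr(rows, "models") <- trained
  rows
}
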