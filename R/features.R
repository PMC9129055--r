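#' Build a subject-by-feature matrix from activity maps
#'
#' Vectorises per-subject activity maps into one row per subject: the
#' in-mask voxels of each requested measure, concatenated in fixed
#' (measure, voxel-index) order. Requesting more than one measure is
#' feature-level fusion by construction. On the full 61 x 73 x 61 grid of
#' 3 mm standard space a single measure contributes 271633 features.
#'
#' @param maps A tibble as returned by [cohort_activity_maps()] (columns
#'   `subject_id`, `label`, `measure`, `map`).
#' @param mask The shared [brain_mask()].
#' @param measures Character vector of measures to include, in block order.
#' @return A `feature_matrix`: list with `values` (subjects x features
#'   numeric matrix), `labels` (factor patient/control), `subject_id`, and
#'   `provenance` (tibble: `measure`, `x`, `y`, `z` per feature).
#' @export
maps_to_feature_matrix <- function(maps, mask, measures = unique(maps$measure)) {
  if (length(measures) == 0) stop("at least one measure must be requested")
  subjects <- unique(maps$subject_id)
  inmask <- which(mask$data)
  coord <- arrayInd(inmask, dim(mask$data))
  blocks <- list(); prov <- list()
  for (m in measures) {
    sub <- maps[maps$measure == m, ]
    if (!setequal(sub$subject_id, subjects) || nrow(sub) != length(subjects))
      stop(sprintf("missing or duplicated %s map for some subject", m))
    sub <- sub[match(subjects, sub$subject_id), ]
    rows <- t(vapply(sub$map, function(mp) {
      if (!all(dim(mp$data) == dim(mask$data)))
        stop("map grid does not match the mask")
      mp$data[inmask]
    }, numeric(length(inmask))))
    blocks[[m]] <- rows
    prov[[m]] <- tibble::tibble(measure = m, x = coord[, 1], y = coord[, 2],
                                z = coord[, 3])
  }
  lab <- maps$label[match(subjects, maps$subject_id)]
  feature_matrix(do.call(cbind, blocks), lab, dplyr::bind_rows(prov), subjects)
}

#' Construct a feature matrix
#'
#' @param values Subjects x features numeric matrix (no missing values).
#' @param labels Factor or character vector of `"patient"` / `"control"`.
#' @param provenance Optional per-feature tibble (defaults to feature index).
#' @param subject_id Optional subject identifiers.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels, provenance = NULL, subject_id = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrices must have no missing values")
  labels <- factor(as.character(labels), levels = c("patient", "control"))
  stopifnot(length(labels) == nrow(values))
  if (any(table(labels) < 2)) stop("need at least 2 subjects per class")
  provenance <- provenance %||%
    tibble::tibble(measure = NA_character_, x = NA_integer_,
                   y = NA_integer_, z = NA_integer_,
                   .rows = ncol(values))
  if (nrow(provenance) != ncol(values))
    stop("provenance length must equal the feature count")
  structure(list(values = values, labels = labels,
                 provenance = provenance,
                 subject_id = subject_id %||% paste0("sub-", seq_len(nrow(values)))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects (%d patients / %d controls) x %d features\n",
              nrow(x$values), sum(x$labels == "patient"),
              sum(x$labels == "control"), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id, label = x$labels),
                   tibble::as_tibble(x$values, .name_repair = "minimal"))
}

# Subset a feature matrix by subject rows and/or feature columns.
fm_subset <- function(x, subjects = NULL, features = NULL) {
  v <- x$values
  lab <- x$labels
  sid <- x$subject_id
  prov <- x$provenance
  if (!is.null(subjects)) {
    v <- v[subjects, , drop = FALSE]; lab <- lab[subjects]; sid <- sid[subjects]
  }
  if (!is.null(features)) {
    v <- v[, features, drop = FALSE]; prov <- prov[features, , drop = FALSE]
  }
  structure(list(values = v, labels = droplevels(lab, exclude = NULL),
                 provenance = prov, subject_id = sid),
            class = "feature_matrix")
}

ranked_features <- function(order, scores, method) {
  scores <- unname(scores)
  stopifnot(length(order) == length(scores),
            setequal(order, seq_along(order)))
  structure(
    tibble::tibble(rank = seq_along(order), feature = as.integer(order),
                   score = scores[order]),
    method = method,
    class = c("ranked_features", class(tibble::tibble()))
  )
}

# descending by score, ties broken by ascending feature index
order_desc_ties_by_index <- function(scores) {
  order(-scores, seq_along(scores))
}

# Column-wise z-scoring with training statistics (sample sd; constant
# columns get sd 1 so they map to 0).
standardize_columns <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, stats::sd)
  scale[scale < .Machine$double.eps] <- 1
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' FSV parameters
#'
#' Knobs of feature selection via concave minimisation: the objective
#' trades average class slacks (weight `1 - lambda`) against the concave
#' feature-suppression term `lambda * sum(1 - exp(-alpha v_j))`.
#'
#' @param lambda Trade-off in (0, 1); default 0.5.
#' @param alpha Concavity parameter (> 0); default 5.
#' @param max_iters Maximum successive-linearisation iterations.
#' @param tol Convergence tolerance on `max |v_new - v_old|`.
#' @return An object of class `fsv_params`.
#' @export
fsv_params <- function(lambda = 0.5, alpha = 5, max_iters = 50, tol = 1e-6) {
  stopifnot(lambda > 0, lambda < 1, alpha > 0, max_iters >= 1, tol >= 0)
  structure(list(lambda = lambda, alpha = alpha, max_iters = max_iters,
                 tol = tol), class = "fsv_params")
}

# One FSV linearised LP. Minimises
#   (1-lambda) (sum(y)/m1 + sum(z)/m2) + sum(grad_j * v_j)
# over w (free), gamma (free), y, z, v >= 0 subject to
#   -A w + gamma e + e <= y   (class A rows)
#    B w - gamma e + e <= z   (class B rows)
#   -v <= w <= v.
# Variables for boot::simplex (all >= 0): [wp, wn, gp, gn, y, z, v].
fsv_lp <- function(a_mat, b_mat, lambda, grad) {
  m1 <- nrow(a_mat); m2 <- nrow(b_mat); p <- ncol(a_mat)
  nv <- 3 * p + 2 + m1 + m2
  i_wp <- 1:p; i_wn <- p + 1:p; i_gp <- 2 * p + 1; i_gn <- 2 * p + 2
  i_y <- (2 * p + 2) + 1:m1; i_z <- (2 * p + 2 + m1) + 1:m2
  i_v <- (2 * p + 2 + m1 + m2) + 1:p
  obj <- numeric(nv)
  obj[i_y] <- (1 - lambda) / m1
  obj[i_z] <- (1 - lambda) / m2
  obj[i_v] <- grad
  # envelope constraints w - v <= 0 and -w - v <= 0 (rhs 0, "<=" block)
  A1 <- matrix(0, 2 * p, nv)
  r <- 1:p
  A1[cbind(r, i_wp)] <- 1; A1[cbind(r, i_wn)] <- -1; A1[cbind(r, i_v)] <- -1
  r <- p + 1:p
  A1[cbind(r, i_wp)] <- -1; A1[cbind(r, i_wn)] <- 1; A1[cbind(r, i_v)] <- -1
  b1 <- numeric(2 * p)
  # separation constraints as ">=" rows (boot::simplex needs rhs >= 0):
  #   a_i w - gamma + y_i >= 1,   -b_i w + gamma + z_i >= 1
  A2 <- matrix(0, m1 + m2, nv)
  A2[1:m1, i_wp] <- a_mat; A2[1:m1, i_wn] <- -a_mat
  A2[1:m1, i_gp] <- -1; A2[1:m1, i_gn] <- 1
  A2[cbind(1:m1, i_y)] <- 1
  r <- m1 + 1:m2
  A2[r, i_wp] <- -b_mat; A2[r, i_wn] <- b_mat
  A2[r, i_gp] <- 1; A2[r, i_gn] <- -1
  A2[cbind(r, i_z)] <- 1
  b2 <- rep(1, m1 + m2)
  sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = FALSE, n.iter = 50 * nv)
  if (sol$solved == -1) stop("FSV linear program did not solve")
  x <- sol$soln
  list(w = x[i_wp] - x[i_wn], gamma = x[i_gp] - x[i_gn], v = x[i_v])
}

#' Rank features by concave minimisation (FSV)
#'
#' Solves the sparse linear-separation problem
#' \deqn{\min_{w,\gamma,y,z,v} (1-\lambda)\left(\frac{e'y}{m_1} +
#'   \frac{e'z}{m_2}\right) + \lambda \sum_j (1 - e^{-\alpha v_j})}
#' subject to the two class-separation constraint sets with non-negative
#' slacks y, z and the envelope \eqn{-v \le w \le v}, by successive
#' linearisation: each iteration replaces the concave term by its gradient
#' \eqn{\alpha e^{-\alpha v_j^{(k)}}} at the previous iterate and solves the
#' resulting linear program, until the v-iterates move by at most `tol` in
#' the max norm or `max_iters` is reached. Features are standardised with
#' their own statistics first; scores are the final envelope values v, and
#' the ranking is by descending score with ties broken by feature index.
#'
#' The dense simplex backend makes this practical for problems up to a few
#' dozen features; pre-reduce wider matrices (e.g. by [rank_wilcoxon()])
#' before applying it.
#'
#' @param x A `feature_matrix` with both classes present.
#' @param params An [fsv_params()].
#' @return A `ranked_features` tibble (`rank`, `feature`, `score`), with
#'   attributes `method = "fsv"` and `converged`.
#' @export
rank_fsv <- function(x, params = fsv_params()) {
  v <- standardize_columns(x$values)$x
  a_mat <- v[x$labels == "patient", , drop = FALSE]
  b_mat <- v[x$labels == "control", , drop = FALSE]
  p <- ncol(v)
  vcur <- rep(0, p)
  converged <- FALSE
  for (k in seq_len(params$max_iters)) {
    # start from the slack-only (robust separation) solution: a near-zero
    # first-iteration gradient avoids the spurious all-zero fixed point of
    # the linearisation at v = 0
    grad <- if (k == 1) rep(1e-8, p)
            else params$lambda * params$alpha * exp(-params$alpha * vcur)
    sol <- fsv_lp(a_mat, b_mat, params$lambda, grad)
    if (max(abs(sol$v - vcur)) <= params$tol) {
      vcur <- sol$v
      converged <- TRUE
      break
    }
    vcur <- sol$v
  }
  if (!converged)
    warning("FSV successive linearisation did not converge; returning last iterate")
  rf <- ranked_features(order_desc_ties_by_index(vcur), vcur, "fsv")
  attr(rf, "converged") <- converged
  rf
}

#' Rank features by an L0-norm approximation
#'
#' Iterative rescaling of a trained soft-margin linear classifier: train on
#' the current rescaled features, multiply each feature's scale by the
#' absolute weight |w_j|, and repeat until the scales stabilise (relative
#' change below 1e-6) or `max_rounds` is reached. The accumulated scales are
#' the scores. With `max_rounds = 1` the ranking is by |w| of a single
#' trained classifier. If the weights collapse to all zeros the first
#' round's |w| is used.
#'
#' @param x A `feature_matrix`.
#' @param max_rounds Maximum rescaling rounds.
#' @param C Soft-margin penalty of the inner classifier.
#' @return A `ranked_features` tibble with method `"l0"`.
#' @export
rank_l0 <- function(x, max_rounds = 20, C = 10) {
  v <- standardize_columns(x$values)$x
  p <- ncol(v)
  scales <- rep(1, p)
  first_absw <- NULL
  for (round in seq_len(max_rounds)) {
    model <- svm_weights(sweep(v, 2, scales, "*"), x$labels, C)
    absw <- abs(model$w)
    if (is.null(first_absw)) first_absw <- absw
    if (all(absw < .Machine$double.eps)) {
      scales <- first_absw
      break
    }
    new_scales <- scales * absw
    if (max(new_scales) > 0) new_scales <- new_scales / max(new_scales)
    rel <- max(abs(new_scales - scales)) / max(max(scales), .Machine$double.eps)
    scales <- new_scales
    if (rel < 1e-6) break
  }
  ranked_features(order_desc_ties_by_index(scales), scales, "l0")
}

#' Rank features by Relief
#'
#' Classic Relief for two classes: features are min-max scaled to `[0, 1]`;
#' for each sampled subject the nearest hit (same class) and nearest miss
#' (other class) under Euclidean distance are found and each feature weight
#' is updated by `|x_j - miss_j| - |x_j - hit_j|`. Scores are the summed
#' updates divided by the number of sampled subjects. By default all
#' subjects are used (in which case the result is deterministic); subjects
#' whose class has no other member are skipped with a warning.
#'
#' @param x A `feature_matrix`.
#' @param n_sample Number of subjects to sample (default: all, in order).
#' @param relief_seed Seed used when `n_sample <` the subject count.
#' @return A `ranked_features` tibble with method `"relief"`.
#' @export
rank_relief <- function(x, n_sample = nrow(x$values), relief_seed = 1) {
  v <- x$values
  rng <- apply(v, 2, function(col) diff(range(col)))
  rng[rng < .Machine$double.eps] <- 1
  v <- sweep(sweep(v, 2, apply(x$values, 2, min)), 2, rng, "/")
  n <- nrow(v); p <- ncol(v)
  if (n_sample < n) {
    set.seed(as.integer(relief_seed %% 2147483647))
    picks <- sample.int(n, n_sample)
  } else {
    picks <- seq_len(n)
    n_sample <- n
  }
  w <- numeric(p)
  used <- 0L
  for (i in picks) {
    same <- which(x$labels == x$labels[i]); same <- setdiff(same, i)
    other <- which(x$labels != x$labels[i])
    if (length(same) == 0L) {
      warning("subject with no same-class partner skipped in Relief")
      next
    }
    d2 <- function(j) sum((v[i, ] - v[j, ])^2)
    hit <- same[which.min(vapply(same, d2, numeric(1)))]
    miss <- other[which.min(vapply(other, d2, numeric(1)))]
    w <- w + abs(v[i, ] - v[miss, ]) - abs(v[i, ] - v[hit, ])
    used <- used + 1L
  }
  scores <- w / max(used, 1L)
  ranked_features(order_desc_ties_by_index(scores), scores, "relief")
}

# Two-sided Wilcoxon rank-sum p-value for one feature. Exact enumeration
# (via the null rank-sum distribution) when both groups have <= 10 subjects
# and the feature has no ties; otherwise normal approximation with tie
# correction. Constant features get p = 1.
wilcoxon_p <- function(vals, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  if (diff(range(vals)) < .Machine$double.eps) return(1)
  r <- rank(vals)
  u <- sum(r[is_a]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of group A
  ties <- any(duplicated(vals))
  if (n1 <= 10 && n2 <= 10 && !ties) {
    p <- if (u > n1 * n2 / 2) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    return(min(p, 1))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(vals)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Rank features by the Wilcoxon rank-sum test
#'
#' Per feature, the two-sided Wilcoxon rank-sum p-value between patients and
#' controls: exact enumeration when both groups have at most 10 subjects and
#' the feature is tie-free, a tie-corrected normal approximation otherwise.
#' Features are ordered by ascending p-value with ties broken by index;
#' scores are `-p` so that, as for all rankers, larger scores rank first.
#'
#' @param x A `feature_matrix`.
#' @return A `ranked_features` tibble with method `"wilcoxon"` carrying a
#'   `p_value` column.
#' @export
rank_wilcoxon <- function(x) {
  is_a <- x$labels == "patient"
  pv <- apply(x$values, 2, wilcoxon_p, is_a = is_a)
  rf <- ranked_features(order_desc_ties_by_index(-pv), -pv, "wilcoxon")
  rf$p_value <- pv[rf$feature]
  rf
}

#' Rank features with a named method
#'
#' @param x A `feature_matrix`.
#' @param method One of `"fsv"`, `"l0"`, `"relief"`, `"wilcoxon"`.
#' @param ... Passed to the method's ranking function.
#' @return A `ranked_features` tibble.
#' @export
rank_features <- function(x, method = c("wilcoxon", "fsv", "l0", "relief"), ...) {
  method <- match.arg(method)
  switch(method,
         fsv = rank_fsv(x, ...),
         l0 = rank_l0(x, ...),
         relief = rank_relief(x, ...),
         wilcoxon = rank_wilcoxon(x))
}

#' Sequential forward selection of the feature count
#'
#' Evaluates the top-k features of a ranking for k = 1..`k_max` with a
#' caller-supplied validation evaluator and returns the smallest k attaining
#' the maximum validation accuracy.
#'
#' @param ranked A `ranked_features` tibble.
#' @param evaluator Function `k -> validation accuracy`, deterministic for
#'   fixed folds.
#' @param k_max Largest feature count to try (>= 1, at most the feature
#'   count).
#' @return A list with `k` (the selected count), `accuracy` (its validation
#'   accuracy) and `profile` (tibble of k vs accuracy).
#' @export
sequential_forward_select <- function(ranked, evaluator, k_max) {
  if (k_max < 1) stop("k_max must be at least 1")
  if (k_max > nrow(ranked)) stop("k_max exceeds the feature count")
  acc <- vapply(seq_len(k_max), function(k) evaluator(k), numeric(1))
  k_star <- which.max(acc)  # which.max returns the first (smallest-k) maximum
  list(k = k_star, accuracy = acc[k_star],
       profile = tibble::tibble(k = seq_len(k_max), accuracy = acc))
}
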