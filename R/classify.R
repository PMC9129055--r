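# Fit a soft-margin linear SVM on an (already standardised) matrix and
# return the primal weight vector and offset with the convention
# d(x) = w.x - gamma, d >= 0 => patient. libsvm orients its decision values
# by the first class it encounters, so we re-orient explicitly.
svm_weights <- function(values, labels, C) {
  y <- factor(as.character(labels), levels = c("patient", "control"))
  fit <- e1071::svm(x = values, y = y, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = 1e-8)
  w <- drop(t(fit$coefs) %*% fit$SV)
  gamma <- fit$rho
  # libsvm orients decision values by the first class it encountered; the
  # column name of the decision values says which class is positive.
  dv <- attr(stats::predict(fit, values[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  if (!startsWith(colnames(dv)[1], "patient")) {
    w <- -w; gamma <- -gamma
  }
  list(w = w, gamma = gamma, fit = fit)
}

#' Train a soft-margin linear classifier
#'
#' Fits the hinge-loss maximum-margin linear separator with penalty `C`
#' (default 10) on column-standardised features; the standardisation
#' statistics are computed on the training subjects and stored with the
#' model so they are re-applied verbatim at prediction time. The decision
#' value is `d(x) = w . x - gamma`, and `d >= 0` classifies as patient.
#'
#' @param x A `feature_matrix` with both classes present.
#' @param C Positive soft-margin penalty.
#' @return An object of class `linear_model` with elements `weights`,
#'   `offset`, `C`, `feature_ids` (provenance tibble) and `center`/`scale`.
#' @export
train_linear <- function(x, C = 10) {
  if (nlevels(droplevels(x$labels)) < 2) stop("training needs both classes")
  if (C <= 0) stop("C must be positive")
  std <- standardize_columns(x$values)
  sw <- svm_weights(std$x, x$labels, C)
  structure(list(weights = sw$w, offset = sw$gamma, C = C,
                 feature_ids = x$provenance,
                 center = std$center, scale = std$scale),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model> %d features, C = %g, offset %.4g\n",
              length(x$weights), x$C, x$offset))
  invisible(x)
}

#' @method tidy linear_model
#' @export
tidy.linear_model <- function(x, ...) {
  dplyr::bind_cols(x$feature_ids,
                   tibble::tibble(weight = unname(x$weights)))
}

#' @method glance linear_model
#' @export
glance.linear_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights), C = x$C,
                 offset = x$offset, l2_norm = sqrt(sum(x$weights^2)))
}

#' Predict labels for new subjects
#'
#' Applies the stored training standardisation, computes the decision value
#' `d(x) = w . x - gamma`, and labels `d >= 0` as patient.
#'
#' @param object A `linear_model`.
#' @param newdata A `feature_matrix` (or bare matrix) whose columns match
#'   the model's training features.
#' @param ... Unused.
#' @return A tibble with `subject_id`, `label` (predicted) and
#'   `decision_value`.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "feature_matrix")) newdata$values else as.matrix(newdata)
  if (ncol(v) != length(object$weights))
    stop("feature columns do not match the trained model")
  vs <- sweep(sweep(v, 2, object$center), 2, object$scale, "/")
  d <- drop(vs %*% object$weights) - object$offset
  tibble::tibble(
    subject_id = if (inherits(newdata, "feature_matrix")) newdata$subject_id
                 else paste0("sub-", seq_len(nrow(v))),
    label = factor(ifelse(d >= 0, "patient", "control"),
                   levels = c("patient", "control")),
    decision_value = d
  )
}

#' Decision-level fusion by majority vote
#'
#' Each subject must have exactly three votes (an odd panel, so no ties);
#' the fused label is the one held by at least two voters.
#'
#' @param votes An n x 3 matrix or data frame of labels
#'   (`"patient"`/`"control"`), one row per subject.
#' @return A factor of fused labels.
#' @export
majority_vote <- function(votes) {
  votes <- as.matrix(as.data.frame(lapply(as.data.frame(votes), as.character)))
  if (ncol(votes) != 3) stop("majority voting expects exactly 3 votes per subject")
  if (!all(votes %in% c("patient", "control")))
    stop("votes must be 'patient' or 'control'")
  n_pat <- rowSums(votes == "patient")
  factor(ifelse(n_pat >= 2, "patient", "control"),
         levels = c("patient", "control"))
}

#' Feature-level fusion by column concatenation
#'
#' Concatenates the feature blocks of several matrices over the same
#' subjects, preserving provenance in input order. Downstream selection then
#' operates on the fused matrix. Duplicated provenance rows (e.g. fusing a
#' matrix with itself) are permitted with a warning.
#'
#' @param x_list List of `feature_matrix` objects with identical subjects in
#'   identical order.
#' @return A fused `feature_matrix`.
#' @export
feature_fusion <- function(x_list) {
  stopifnot(length(x_list) >= 1)
  first <- x_list[[1]]
  for (x in x_list[-1]) {
    if (!identical(x$subject_id, first$subject_id) ||
        !identical(as.character(x$labels), as.character(first$labels)))
      stop("all matrices must carry the same subjects in the same order")
  }
  prov <- dplyr::bind_rows(lapply(x_list, `[[`, "provenance"))
  known <- prov[!is.na(prov$measure), , drop = FALSE]
  if (nrow(known) > 0 && anyDuplicated(known) > 0)
    warning("duplicated feature provenance after fusion")
  feature_matrix(do.call(cbind, lapply(x_list, `[[`, "values")),
                 first$labels, prov, first$subject_id)
}

#' Serialize / restore a linear model as JSON
#'
#' @param model A `linear_model`.
#' @param path File path.
#' @return `write_linear_model()` returns `path` invisibly;
#'   `read_linear_model()` returns the restored `linear_model`.
#' @export
write_linear_model <- function(model, path) {
  obj <- list(weights = unname(model$weights), offset = model$offset,
              C = model$C, center = unname(model$center),
              scale = unname(model$scale),
              feature_ids = as.data.frame(model$feature_ids))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(obj$weights), offset = obj$offset,
                 C = obj$C, feature_ids = tibble::as_tibble(obj$feature_ids),
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale)),
            class = "linear_model")
}
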