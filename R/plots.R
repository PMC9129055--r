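#' Plot an ROC curve
#'
#' @param object A [roc_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of an activity map
#'
#' @param object An [activity_map()].
#' @param slice Z index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot activity_map
#' @export
autoplot.activity_map <- function(object, slice = NULL, ...) {
  d <- dim(object$data)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$data[, , slice])
  df$value[!as.vector(object$mask$data[, , slice])] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, z = %d", toupper(object$measure), slice),
                  fill = object$measure) +
    ggplot2::theme_minimal()
}

#' Plot the vertically averaged ROC of a cross-validation report
#'
#' @param report A `cv_report` from [nested_cv()].
#' @return A ggplot object annotated with the AUC.
#' @export
plot_cv_roc <- function(report) {
  stopifnot(inherits(report, "cv_report"), !is.null(report$roc))
  autoplot.roc_curve(report$roc$curve) +
    ggplot2::geom_line() +
    ggplot2::labs(subtitle = sprintf("Vertically averaged, AUC = %.3f",
                                     report$roc$auc))
}

#' Plot Rician-noise robustness
#'
#' @param robustness Tibble from [rician_robustness()].
#' @return A ggplot object (metric vs sigma).
#' @export
plot_robustness <- function(robustness) {
  long <- tidyr::pivot_longer(robustness,
                              cols = c("accuracy", "sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sigma, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(sigma), y = NULL) +
    ggplot2::theme_minimal()
}
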