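#' Plot a perfusion profile
#'
#' Time course of the profile value with the occlusion window shaded and
#' the release marked, the standard way these series are inspected.
#'
#' @param object A [perfusion_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perfusion_profile <- function(object, ...) {
  d <- object$data
  ev <- object$events
  ylab <- switch(object$unit,
    percent = "R-B change from baseline (%)",
    F = "Mean leg temperature (°F)",
    "Mean ROI intensity"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::annotate("rect",
      xmin = ev[["occlusion_start"]], xmax = ev[["release"]],
      ymin = -Inf, ymax = Inf, alpha = 0.12
    ) +
    ggplot2::geom_vline(xintercept = ev[["release"]], linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Time (min)", y = ylab,
      title = sprintf("%s perfusion profile", object$modality)
    ) +
    ggplot2::theme_minimal()
}

#' Plot calibration and cross-validation ROC curves
#'
#' @param object A `plsda_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot with the resubstitution (calibration) ROC in black and
#'   the pooled out-of-fold (cross-validation) ROC in gray, AUCs in the
#'   legend.
#' @export
autoplot.plsda_cv <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$calibration$roc,
                  set = sprintf("Calibration (AUC %.2f)", object$calibration$auc)),
    dplyr::mutate(object$pooled$roc,
                  set = sprintf("Cross-validation (AUC %.2f)", object$pooled$auc))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr, color = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::scale_color_manual(values = c("black", "gray55")) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
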