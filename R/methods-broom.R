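#' Tidy a fitted PLSDA model
#'
#' One row per feature and latent variable, with the NIPALS weight, the
#' loading, and the feature's contribution to the regression vector.
#'
#' @param x A `plsda` model.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `component`, `weight`,
#'   `loading`, `coefficient`.
#' @export
tidy.plsda <- function(x, ...) {
  purrr::map_dfr(seq_len(x$ncomp), function(a) {
    tibble(
      feature = x$features %||% paste0("x", seq_along(x$b)),
      component = a,
      weight = x$W[, a],
      loading = x$P[, a],
      coefficient = x$b
    )
  })
}

#' @rdname tidy.plsda
#' @export
glance.plsda <- function(x, ...) {
  tibble(
    ncomp = x$ncomp,
    n_features = length(x$b),
    n_samples = nrow(x$Tscores),
    positive = x$positive,
    threshold = x$threshold,
    response_mean = x$y_mean
  )
}

#' Tidy cross-validation results
#'
#' @param x A `plsda_cv` object.
#' @param ... Unused.
#' @return `tidy()`: per-iteration confusion counts, sensitivity,
#'   specificity and AUC. `glance()`: one row with the iteration-averaged
#'   CV metrics and the calibration metrics.
#' @export
tidy.plsda_cv <- function(x, ...) x$iterations

#' @rdname tidy.plsda_cv
#' @export
glance.plsda_cv <- function(x, ...) {
  tibble(
    ncomp = x$settings$ncomp,
    n_iterations = x$settings$n_iterations,
    n_splits = x$settings$n_splits,
    cv_sensitivity = x$cv$sensitivity,
    cv_specificity = x$cv$specificity,
    cv_auc = x$cv$auc,
    pooled_auc = x$pooled$auc,
    cal_sensitivity = x$calibration$confusion$sensitivity,
    cal_specificity = x$calibration$confusion$specificity,
    cal_auc = x$calibration$auc,
    n_excluded = nrow(x$exclusion_log)
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [one_way_anova()] or
#'   [kruskal_wallis()].
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value and tier (plus the
#'   pairwise table nested in a list column for ANOVA).
#' @export
tidy.group_comparison <- function(x, ...) {
  out <- tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    tier = x$tier
  )
  if (!is.null(x$pairwise)) out$pairwise <- list(x$pairwise)
  out
}
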