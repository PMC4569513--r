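#' Drop animals with excessive missing data and impute the rest
#'
#' Rows whose feature-missingness fraction exceeds `max_missing_fraction`,
#' or whose outcome label is missing, are excluded (with a reason logged);
#' remaining missing cells are imputed by the column mean of the retained
#' rows. Cross-validation refits the imputation inside each training fold
#' instead (`impute = FALSE`).
#'
#' @param data Tibble with an id column, an outcome column, and numeric
#'   feature columns.
#' @param features Character vector of feature column names; default all
#'   numeric columns other than `id` and `outcome`.
#' @param outcome,id Column names (strings) of the outcome label and the
#'   animal id.
#' @param max_missing_fraction Row-missingness threshold in `[0, 1]`;
#'   default 0.2.
#' @param impute Impute remaining missing cells by retained-column means.
#' @return List with `data` (retained, possibly imputed, tibble) and `log`
#'   (tibble of excluded ids and reasons).
#' @export
exclude_missing <- function(data, features = NULL, outcome = "outcome",
                            id = "animal_id", max_missing_fraction = 0.2,
                            impute = TRUE) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  features <- features %||% feature_columns(data, outcome, id)
  x <- as.matrix(data[, features])
  miss_frac <- rowMeans(is.na(x))
  no_outcome <- is.na(data[[outcome]])
  drop <- no_outcome | miss_frac > max_missing_fraction
  log <- tibble(
    animal_id = data[[id]][drop],
    reason = ifelse(no_outcome[drop], "missing_outcome", "excess_missing_features"),
    missing_fraction = miss_frac[drop]
  )
  kept <- data[!drop, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop_limbperf("All rows were excluded for missing data.", "limbperf_validation_error")
  }
  if (impute) {
    for (f in features) {
      v <- kept[[f]]
      if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
      kept[[f]] <- v
    }
  }
  list(data = kept, log = log)
}

feature_columns <- function(data, outcome, id) {
  cand <- setdiff(names(data), c(outcome, id))
  cand[vapply(data[cand], is.numeric, logical(1))]
}

#' Mean-center a feature matrix
#'
#' @param x Numeric matrix with no missing cells.
#' @return List with `x_centered` (every column mean 0) and `means`, the
#'   column means to apply to new samples.
#' @export
mean_center <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_limbperf("mean_center() requires complete data.", "limbperf_validation_error")
  means <- colMeans(x)
  list(x_centered = sweep(x, 2, means), means = means)
}

# code a two-class outcome as -1/+1 with the positive (detection) class +1
code_classes <- function(y, positive = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y[!is.na(y)]))
  if (length(classes) != 2) {
    stop_limbperf("Outcome must have exactly two classes.", "limbperf_validation_error")
  }
  positive <- positive %||% if ("not_recovered" %in% classes) "not_recovered" else classes[2]
  if (!positive %in% classes) {
    stop_limbperf("`positive` is not one of the outcome classes.", "limbperf_validation_error")
  }
  negative <- setdiff(classes, positive)
  list(coded = ifelse(y == positive, 1, -1), positive = positive, negative = negative)
}

#' Fit a two-class PLS discriminant model
#'
#' Partial least squares discriminant analysis: the two outcome classes are
#' coded as a -1/+1 response, predictors are mean-centered (centering only
#' — no autoscaling), and latent variables are extracted by the NIPALS
#' iteration: weight `w = X'y / ||X'y||`, scores `t = X w`, loadings
#' `p = X't / t't`, response loading `q = t'y / t't`, then deflation
#' `X <- X - t p'`, `y <- y - t q`. The regression vector is assembled as
#' `b = W (P'W)^{-1} q`, and the continuous predicted response is
#' `yhat = (X - means) b + mean(y)` — a signed score whose sign side of the
#' decision threshold assigns the class.
#'
#' @param x Numeric feature matrix (rows = animals), complete.
#' @param y Two-class outcome (character/factor), or numeric -1/+1.
#' @param ncomp Number of latent variables, 1 or 2.
#' @param positive Label of the detection-target class, coded +1. Default
#'   `"not_recovered"` when present.
#' @param threshold Decision threshold on the continuous response; default
#'   0, the midpoint of the -1/+1 coding. Scores at or above the threshold
#'   are assigned to the positive class, so an exact tie goes to "not
#'   recovered" under the defaults — the conservative call.
#' @return Object of class `plsda`: centering means, weight/score/loading
#'   matrices (`W`, `Tscores`, `P`), response loadings `q`, regression
#'   vector `b`, response mean, class coding, threshold.
#' @export
fit_plsda <- function(x, y, ncomp = 2, positive = NULL, threshold = 0) {
  x <- as.matrix(x)
  if (!ncomp %in% c(1L, 2L)) {
    stop_limbperf("ncomp must be 1 or 2.", "limbperf_validation_error")
  }
  if (anyNA(x)) stop_limbperf("fit_plsda() requires complete data.", "limbperf_validation_error")
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    coding <- list(coded = y, positive = "+1", negative = "-1")
  } else {
    coding <- code_classes(y, positive)
  }
  if (min(table(coding$coded)) < 2) {
    stop_limbperf("Each class needs at least two samples.", "limbperf_validation_error")
  }
  if (all(apply(x, 2, sd) == 0)) {
    stop_limbperf("All features have zero variance.", "limbperf_validation_error")
  }
  cen <- mean_center(x)
  Xd <- cen$x_centered
  y_mean <- mean(coding$coded)
  yd <- coding$coded - y_mean

  p <- ncol(x)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Ts <- matrix(0, nrow(x), ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop_limbperf(
        sprintf("Latent variable %d is not identifiable (rank exhausted).", a),
        "limbperf_rank_error"
      )
    }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) {
      stop_limbperf(
        sprintf("Latent variable %d has zero score variance (rank exhausted).", a),
        "limbperf_rank_error"
      )
    }
    pv <- drop(crossprod(Xd, tt)) / tt2
    qa <- sum(tt * yd) / tt2
    Xd <- Xd - tcrossprod(tt, pv)
    yd <- yd - tt * qa
    W[, a] <- w; P[, a] <- pv; Ts[, a] <- tt; q[a] <- qa
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(
    list(means = cen$means, y_mean = y_mean, W = W, P = P, Tscores = Ts,
         q = q, b = b, ncomp = ncomp, threshold = threshold,
         positive = coding$positive, negative = coding$negative,
         features = colnames(x)),
    class = "plsda"
  )
}

#' Predict from a fitted PLSDA model
#'
#' @param object A [fit_plsda()] model.
#' @param newdata Numeric matrix or data frame with the training feature
#'   columns.
#' @param ... Unused.
#' @return Tibble with the continuous `score` and the hard `class` label
#'   (scores at or above the threshold go to the positive class).
#' @export
predict.plsda <- function(object, newdata, ...) {
  x <- as.matrix(as_tibble(newdata)[, object$features, drop = FALSE])
  if (ncol(x) != length(object$means)) {
    stop_limbperf("newdata feature columns do not match the training features.",
                  "limbperf_validation_error")
  }
  score <- drop(sweep(x, 2, object$means) %*% object$b) + object$y_mean
  tibble(
    score = score,
    class = ifelse(score >= object$threshold, object$positive, object$negative)
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d latent variable(s), %d features, positive class '%s'\n",
              x$ncomp, length(x$features), x$positive))
  invisible(x)
}

#' @rdname fit_plsda
#' @param data Tibble with id, outcome, and feature columns (tidy front end
#'   to [fit_plsda()]).
#' @param outcome,id Column names (strings).
#' @param features Feature column names; default all other numeric columns.
#' @export
plsda_fit <- function(data, outcome = "outcome", id = "animal_id",
                      features = NULL, ncomp = 2, positive = NULL, threshold = 0) {
  features <- features %||% feature_columns(data, outcome, id)
  fit_plsda(as.matrix(data[, features]), data[[outcome]],
            ncomp = ncomp, positive = positive, threshold = threshold)
}

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over every observed score to trace the
#' receiver operating characteristic, and computes the AUC by the
#' rank-based Mann-Whitney statistic, which equals the trapezoidal area and
#' gives tied score pairs half credit.
#'
#' @param scores Continuous classifier scores; larger = more positive.
#' @param truth Logical (or two-class) vector of true labels; `TRUE`/the
#'   positive class marks positives.
#' @param positive Positive label when `truth` is not logical.
#' @return List with `auc` and `roc`, a tibble of (`threshold`, `fpr`,
#'   `tpr`) points with monotone nondecreasing TPR along the sweep.
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  truth <- as_truth(truth, positive)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    stop_limbperf("Both classes must be present to compute a ROC curve.",
                  "limbperf_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- purrr::map_dfr(thr, function(th) {
    pred <- scores >= th
    tibble(threshold = th,
           fpr = sum(pred & !truth) / nneg,
           tpr = sum(pred & truth) / npos)
  })
  list(auc = auc, roc = roc)
}

as_truth <- function(truth, positive = NULL) {
  if (is.logical(truth)) return(truth)
  positive <- positive %||% if ("not_recovered" %in% truth) "not_recovered" else
    sort(unique(as.character(truth)))[2]
  as.character(truth) == positive
}

#' Confusion counts and sensitivity/specificity
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP); both
#' reported as percentages to one decimal place, alongside the raw counts.
#'
#' @param predicted Predicted labels (or logical, `TRUE` = positive).
#' @param truth True labels (or logical).
#' @param positive Positive-class label when inputs are not logical.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity` (percent, one decimal).
#' @export
confusion_stats <- function(predicted, truth, positive = NULL) {
  truth_l <- as_truth(truth, positive)
  pred_l <- as_truth(predicted, positive)
  if (!any(truth_l) || all(truth_l)) {
    stop_limbperf("Both classes must be present in `truth`.", "limbperf_validation_error")
  }
  tp <- sum(pred_l & truth_l); fn <- sum(!pred_l & truth_l)
  tn <- sum(!pred_l & !truth_l); fp <- sum(pred_l & !truth_l)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = round(100 * tp / (tp + fn), 1),
    specificity = round(100 * tn / (tn + fp), 1)
  )
}

#' Random-subset cross-validation of a PLSDA classifier
#'
#' Repeats a 4-fold random partition of the animals for a number of
#' iterations (default 10). Folds are stratified by class by default, so
#' every held-out fold can be scored; each fold is predicted by a model
#' fitted on the remaining animals, with mean-imputation and mean-centering
#' refit inside the training folds only. Per-iteration sensitivity,
#' specificity and AUC are averaged across iterations (the headline CV
#' metrics); the pooled out-of-fold scores and a calibration
#' (resubstitution) fit are reported alongside.
#'
#' @param data Tibble with id, outcome and feature columns.
#' @param outcome,id Column names (strings).
#' @param features Feature column names; default all other numeric columns.
#' @param ncomp Latent variables (1 or 2).
#' @param n_splits Folds per iteration (default 4).
#' @param n_iterations Random repartitions (default 10).
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param max_missing_fraction Row-exclusion threshold, see
#'   [exclude_missing()].
#' @param positive Positive-class label (default `"not_recovered"`).
#' @param threshold Decision threshold on the continuous response.
#' @return Object of class `plsda_cv`: per-iteration metrics, their means
#'   (`cv`), pooled out-of-fold results (`pooled`), the calibration results
#'   (`calibration`), the final model, out-of-fold scores, and the
#'   exclusion log.
#' @export
cross_validate <- function(data, outcome = "outcome", id = "animal_id",
                           features = NULL, ncomp = 2, n_splits = 4,
                           n_iterations = 10, seed = NULL, stratified = TRUE,
                           max_missing_fraction = 0.2, positive = NULL,
                           threshold = 0) {
  features <- features %||% feature_columns(data, outcome, id)
  excl <- exclude_missing(data, features, outcome, id,
                          max_missing_fraction = max_missing_fraction,
                          impute = FALSE)
  d <- excl$data
  y <- as.character(d[[outcome]])
  coding <- code_classes(y, positive)
  pos <- coding$positive
  truth <- y == pos
  if (min(table(truth)) < n_splits) {
    stop_limbperf("Each class needs at least `n_splits` members.", "limbperf_validation_error")
  }

  with_seed(seed, {
    iters <- purrr::map_dfr(seq_len(n_iterations), function(it) {
      fold <- integer(nrow(d))
      if (stratified) {
        for (cl in unique(truth)) {
          idx <- which(truth == cl)
          fold[idx] <- sample(rep_len(seq_len(n_splits), length(idx)))
        }
      } else {
        fold <- sample(rep_len(seq_len(n_splits), nrow(d)))
      }
      oof <- numeric(nrow(d))
      for (k in seq_len(n_splits)) {
        tr <- fold != k
        d_tr <- impute_train_test(d[tr, ], d[!tr, ], features)
        m <- fit_plsda(as.matrix(d_tr$train[, features]), y[tr],
                       ncomp = ncomp, positive = pos, threshold = threshold)
        oof[!tr] <- predict(m, d_tr$test)$score
      }
      cm <- confusion_stats(oof >= threshold, truth)
      ra <- roc_auc(oof, truth)
      dplyr::bind_cols(tibble(iteration = it), cm, tibble(auc = ra$auc),
                       tibble(scores = list(tibble(animal_id = d[[id]],
                                                   score = oof, truth = truth))))
    })
    cal_data <- exclude_missing(data, features, outcome, id,
                                max_missing_fraction = max_missing_fraction,
                                impute = TRUE)$data
    cal_model <- fit_plsda(as.matrix(cal_data[, features]),
                           as.character(cal_data[[outcome]]),
                           ncomp = ncomp, positive = pos, threshold = threshold)
    cal_pred <- predict(cal_model, cal_data)
    cal_truth <- as.character(cal_data[[outcome]]) == pos
    cal_cm <- confusion_stats(cal_pred$class == pos, cal_truth)
    cal_roc <- roc_auc(cal_pred$score, cal_truth)

    pooled_scores <- dplyr::bind_rows(iters$scores)
    pooled_cm <- confusion_stats(pooled_scores$score >= threshold, pooled_scores$truth)
    pooled_roc <- roc_auc(pooled_scores$score, pooled_scores$truth)

    structure(
      list(
        iterations = dplyr::select(iters, -"scores"),
        oof_scores = dplyr::bind_rows(
          purrr::map2(iters$iteration, iters$scores,
                      ~ dplyr::mutate(.y, iteration = .x, .before = 1))
        ),
        cv = list(sensitivity = mean(iters$sensitivity),
                  specificity = mean(iters$specificity),
                  auc = mean(iters$auc)),
        pooled = list(confusion = pooled_cm, auc = pooled_roc$auc,
                      roc = pooled_roc$roc),
        calibration = list(confusion = cal_cm, auc = cal_roc$auc,
                           roc = cal_roc$roc),
        model = cal_model,
        exclusion_log = excl$log,
        settings = list(ncomp = ncomp, n_splits = n_splits,
                        n_iterations = n_iterations, seed = seed,
                        stratified = stratified, positive = pos,
                        threshold = threshold, features = features)
      ),
      class = "plsda_cv"
    )
  })
}

# column-mean imputation fitted on the training fold only
impute_train_test <- function(train, test, features) {
  for (f in features) {
    m <- mean(train[[f]], na.rm = TRUE)
    if (is.nan(m)) m <- 0
    tv <- train[[f]]; tv[is.na(tv)] <- m; train[[f]] <- tv
    sv <- test[[f]]; sv[is.na(sv)] <- m; test[[f]] <- sv
  }
  list(train = train, test = test)
}

#' Choose the latent-variable count by cross-validated AUC
#'
#' Runs [cross_validate()] with one and with two latent variables and keeps
#' the better mean cross-validated AUC (ties favor the simpler model).
#'
#' @inheritParams cross_validate
#' @return The winning `plsda_cv` object, with `settings$ncomp` recording
#'   the choice.
#' @export
select_ncomp <- function(data, ..., seed = NULL) {
  cv1 <- cross_validate(data, ..., ncomp = 1, seed = seed)
  cv2 <- cross_validate(data, ..., ncomp = 2, seed = seed)
  if (cv2$cv$auc > cv1$cv$auc) cv2 else cv1
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf(
    "<plsda_cv> %d LV, %d x %d-fold CV\n  CV:  sens %.1f%%, spec %.1f%%, AUC %.3f\n  Cal: sens %.1f%%, spec %.1f%%, AUC %.3f\n",
    x$settings$ncomp, x$settings$n_iterations, x$settings$n_splits,
    x$cv$sensitivity, x$cv$specificity, x$cv$auc,
    x$calibration$confusion$sensitivity, x$calibration$confusion$specificity,
    x$calibration$auc
  ))
  invisible(x)
}
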