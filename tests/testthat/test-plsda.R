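make_fm <- function(n = 20, p = 5, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("recovered", "not_recovered"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == "not_recovered", 1] <- x[y == "not_recovered", 1] + sep
  colnames(x) <- paste0("f", seq_len(p))
  dplyr::bind_cols(tibble::tibble(animal_id = sprintf("S%02d", 1:n), outcome = y),
                   tibble::as_tibble(x))
}

test_that("exclude_missing drops, logs and imputes as specified", {
  fm <- make_fm(6, 5)
  fm$f1[2] <- NA; fm$f2[2] <- NA    # 40% missing -> dropped at threshold 0.2
  fm$f2[4] <- NA                    # 20% missing -> retained and imputed
  fm$outcome[6] <- NA
  res <- exclude_missing(fm, max_missing_fraction = 0.2)
  expect_setequal(res$log$animal_id, c("S02", "S06"))
  expect_equal(res$log$reason[res$log$animal_id == "S06"], "missing_outcome")
  expect_true("S04" %in% res$data$animal_id)
  expect_false(anyNA(res$data[, paste0("f", 1:5)]))

  # imputation by retained-column mean: (1, 3, NA) -> 2
  fm2 <- make_fm(3, 2)
  fm2$f1 <- c(1, 3, NA)
  out <- exclude_missing(fm2, max_missing_fraction = 0.6)$data
  expect_equal(out$f1[3], 2)

  # untouched row retained
  expect_true("S01" %in% res$data$animal_id)
  # everything excluded -> error
  fm3 <- make_fm(4, 2)
  fm3$outcome <- NA
  expect_error(exclude_missing(fm3), class = "limbperf_validation_error")
})

test_that("mean_center zeroes columns and stores reusable means", {
  mc <- mean_center(cbind(a = c(1, 2, 3), b = c(4, 4, 10)))
  expect_equal(mc$x_centered[, "a"], c(-1, 0, 1))
  expect_equal(unname(mc$means), c(2, 6))
  expect_equal(colMeans(mc$x_centered), c(a = 0, b = 0))
  # idempotence
  mc2 <- mean_center(mc$x_centered)
  expect_equal(mc2$x_centered, mc$x_centered)
  # applying training means to new rows does not re-center them
  x_new <- cbind(a = c(10, 11), b = c(1, 2))
  shifted <- sweep(x_new, 2, mc$means)
  expect_false(all(abs(colMeans(shifted)) < 1e-12))
})

test_that("one-LV PLS direction equals normalized X'y (closed form)", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(8:20, 1); p <- sample(3:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c(-1, 1), length.out = n)
    m <- fit_plsda(x, y, ncomp = 1)
    xc <- scale(x, scale = FALSE)
    yc <- y - mean(y)
    w_oracle <- drop(crossprod(xc, yc))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    cosine <- abs(sum(m$W[, 1] * w_oracle))
    expect_gt(cosine, 1 - 1e-10)
    # the 1-LV regression vector is proportional to the weight vector
    expect_gt(abs(sum(m$b * w_oracle)) / sqrt(sum(m$b^2)), 1 - 1e-10)
  }
})

test_that("rank-1 data recovers the constructing loading direction", {
  set.seed(3)
  t <- rnorm(15)
  p <- c(2, -1, 0.5, 3)
  x <- tcrossprod(t, p)
  m <- fit_plsda(x, sign(t), ncomp = 1)
  cosine <- abs(sum(m$W[, 1] * p)) / sqrt(sum(p^2))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("successive score vectors are orthogonal and X deflates", {
  set.seed(4)
  x <- matrix(rnorm(18 * 6), 18, 6)
  y <- rep(c(-1, 1), 9)
  m <- fit_plsda(x, y, ncomp = 2)
  expect_lt(abs(sum(m$Tscores[, 1] * m$Tscores[, 2])),
            1e-8 * sqrt(sum(m$Tscores[, 1]^2) * sum(m$Tscores[, 2]^2)))
})

test_that("well-separated clusters classify perfectly at resubstitution", {
  fm <- make_fm(20, 5, sep = 6)
  m <- plsda_fit(fm)
  pred <- predict(m, fm)
  expect_equal(pred$class, fm$outcome)
  cm <- confusion_stats(pred$class, fm$outcome)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)
})

test_that("predictions agree with an independent PLS implementation", {
  set.seed(6)
  n <- 16; p <- 5
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c(-1, 1), each = n / 2)
  for (nc in 1:2) {
    mine <- fit_plsda(x, y, ncomp = nc)
    ref <- mixOmics::pls(x, y, ncomp = nc, mode = "regression", scale = FALSE)
    ref_pred <- predict(ref, x)$predict[, 1, nc]
    my_pred <- predict(mine, tibble::as_tibble(x))$score
    expect_equal(unname(my_pred), unname(ref_pred), tolerance = 1e-8)
  }
})

test_that("degenerate fits are refused", {
  x0 <- matrix(1, 10, 3)
  expect_error(fit_plsda(x0, rep(c(-1, 1), 5)), class = "limbperf_error")
  # rank-1 predictors cannot support a second latent variable
  t <- rnorm(12)
  x1 <- tcrossprod(t, c(1, 2, 3))
  expect_error(fit_plsda(x1, sign(t), ncomp = 2), class = "limbperf_rank_error")
  expect_error(fit_plsda(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5), ncomp = 3),
               class = "limbperf_validation_error")
})

test_that("threshold ties and zero rows behave as documented", {
  fm <- make_fm(12, 4, sep = 2, seed = 9)
  m <- plsda_fit(fm)  # balanced classes: response mean is 0
  expect_equal(m$y_mean, 0)
  # a row at the feature means scores exactly the intercept (= y_mean = 0),
  # and the tie goes to the positive, not-recovered class
  at_mean <- tibble::as_tibble(as.list(m$means))
  pred <- predict(m, at_mean)
  expect_equal(pred$score, 0)
  expect_equal(pred$class, "not_recovered")
  # feature mismatch
  expect_error(predict(m, tibble::tibble(bogus = 1)))
})

test_that("roc_auc matches forced cases and brute-force pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "limbperf_validation_error")

  brute <- function(s, t) {
    pos <- s[t]; neg <- s[!t]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    t <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(t) || all(t)) next
    r <- roc_auc(s, t)
    expect_equal(r$auc, brute(s, t))
    expect_true(all(diff(r$roc$tpr) >= 0))
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_equal(r$auc, as.numeric(pROC::auc(pROC::roc(
      t, s, quiet = TRUE, direction = "<"))))
  }
})

test_that("confusion_stats reproduces printed-rate arithmetic", {
  pred <- c(rep(TRUE, 7), rep(FALSE, 1), rep(FALSE, 6), rep(TRUE, 3))
  truth <- c(rep(TRUE, 8), rep(FALSE, 9))
  cm <- confusion_stats(pred, truth)
  expect_equal(cm$tp, 7); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 6); expect_equal(cm$fp, 3)
  expect_equal(cm$sensitivity, 87.5)
  expect_equal(cm$specificity, 66.7)
  expect_equal(confusion_stats(truth, truth)$sensitivity, 100)
  expect_equal(confusion_stats(truth, truth)$specificity, 100)
  all_pos <- confusion_stats(rep(TRUE, 17), truth)
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$specificity, 0)
})

test_that("cross-validation is deterministic, scores every animal, and is exact on separable data", {
  fm <- make_fm(24, 6, sep = 6)
  cv1 <- cross_validate(fm, ncomp = 1, seed = 42)
  cv2 <- cross_validate(fm, ncomp = 1, seed = 42)
  expect_identical(cv1$iterations, cv2$iterations)
  expect_identical(cv1$oof_scores, cv2$oof_scores)
  expect_equal(cv1$cv$sensitivity, 100)
  expect_equal(cv1$cv$specificity, 100)
  expect_equal(cv1$cv$auc, 1)
  # every animal is scored out of fold in every iteration
  expect_equal(nrow(cv1$oof_scores), 10 * 24)
  # per-iteration sensitivity is a multiple of 1/(TP+FN)
  tpfn <- cv1$iterations$tp + cv1$iterations$fn
  expect_true(all(abs(cv1$iterations$sensitivity / 100 * tpfn -
                        round(cv1$iterations$sensitivity / 100 * tpfn)) < 1e-6))
  # class smaller than the fold count
  fm_small <- make_fm(8, 4)[c(1:3, 4:8), ]
  fm_small$outcome <- c(rep("recovered", 3), rep("not_recovered", 5))
  expect_error(cross_validate(fm_small, n_splits = 4),
               class = "limbperf_validation_error")
})

test_that("select_ncomp picks the better cross-validated AUC", {
  fm <- make_fm(24, 6, sep = 4, seed = 13)
  best <- select_ncomp(fm, seed = 7)
  cv1 <- cross_validate(fm, ncomp = 1, seed = 7)
  cv2 <- cross_validate(fm, ncomp = 2, seed = 7)
  expect_equal(best$cv$auc, max(cv1$cv$auc, cv2$cv$auc))
})

test_that("broom methods summarize plsda objects", {
  fm <- make_fm(16, 4)
  m <- plsda_fit(fm, ncomp = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 8)   # 4 features x 2 components
  expect_named(td, c("feature", "component", "weight", "loading", "coefficient"))
  g <- glance(m)
  expect_equal(g$ncomp, 2)
  cv <- cross_validate(fm, seed = 3)
  expect_equal(nrow(tidy(cv)), 10)
  expect_named(glance(cv)[, 1:3], c("ncomp", "n_iterations", "n_splits"))
})
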