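#' Significance tier markers
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise an
#' empty string (or a dagger for p <= 0.1 when `dagger = TRUE`, flagging
#' differences approaching significance in summary tables).
#'
#' @param p Numeric p-values.
#' @param dagger Mark 0.05 < p <= 0.1 with a dagger.
#' @return Character vector of markers.
#' @export
significance_tier <- function(p, dagger = FALSE) {
  out <- dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    dagger & p <= 0.1 ~ "†",
    TRUE ~ ""
  )
  out
}

#' One-way ANOVA across groups with Bonferroni pairwise contrasts
#'
#' Compares a continuous, approximately normal variable across groups by a
#' one-way analysis of variance, followed by all pairwise mean contrasts
#' with Bonferroni-multiplied p-values (capped at 1) using the pooled
#' within-group standard deviation.
#'
#' @param data A data frame, or a list of numeric vectors (one per group).
#' @param value,group Column names (tidy-eval) when `data` is a data frame.
#' @return A `group_comparison` list: `method`, `statistic` (F), `df`,
#'   `p_value`, `tier`, and `pairwise`, a tibble with raw and
#'   Bonferroni-adjusted p-values per group pair.
#' @export
one_way_anova <- function(data, value, group) {
  gl <- as_group_list(data, {{ value }}, {{ group }})
  if (length(gl) < 2) stop_limbperf("Need at least two groups.", "limbperf_validation_error")
  if (any(lengths(gl) < 2)) {
    stop_limbperf("Every group needs n >= 2 for ANOVA.", "limbperf_validation_error")
  }
  df <- tibble(
    value = unlist(gl, use.names = FALSE),
    group = factor(rep(names(gl), lengths(gl)), levels = names(gl))
  )
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (stats::var(df$value) == 0 || !is.finite(fstat)) {
    # no variation anywhere: no evidence of any group difference
    fstat <- 0; p <- 1
  }
  raw <- pairwise.t.test(df$value, df$group, p.adjust.method = "none")$p.value
  adj <- pairwise.t.test(df$value, df$group, p.adjust.method = "bonferroni")$p.value
  raw[is.nan(raw)] <- 1
  adj[is.nan(adj)] <- 1
  pw <- pairwise_tibble(raw, adj)
  structure(
    list(method = "one-way ANOVA", statistic = unname(fstat),
         df = unname(tab[["Df"]]), p_value = unname(p),
         tier = significance_tier(p), pairwise = pw),
    class = "group_comparison"
  )
}

pairwise_tibble <- function(raw, adj) {
  idx <- which(!is.na(raw), arr.ind = TRUE)
  tibble(
    group1 = rownames(raw)[idx[, 1]],
    group2 = colnames(raw)[idx[, 2]],
    p_raw = raw[idx],
    p_adj = pmin(1, adj[idx])
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric group comparison used for ordinal or skewed variables
#' (e.g. tourniquet vs occlusion, recovered vs not recovered). Reports the
#' tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom. A fully tied sample (all values identical) yields H = 0, p = 1
#' rather than an error.
#'
#' @inheritParams one_way_anova
#' @return A `group_comparison` list (no pairwise component).
#' @export
kruskal_wallis <- function(data, value, group) {
  gl <- as_group_list(data, {{ value }}, {{ group }})
  if (length(gl) < 2) stop_limbperf("Need at least two groups.", "limbperf_validation_error")
  x <- unlist(gl, use.names = FALSE)
  if (length(x) < 3) stop_limbperf("Need total n >= 3.", "limbperf_validation_error")
  if (length(unique(x)) == 1L) {
    h <- 0; p <- 1; dfree <- length(gl) - 1
  } else {
    g <- factor(rep(names(gl), lengths(gl)), levels = names(gl))
    kt <- kruskal.test(x, g)
    h <- unname(kt$statistic); p <- unname(kt$p.value); dfree <- unname(kt$parameter)
  }
  structure(
    list(method = "Kruskal-Wallis", statistic = h, df = dfree,
         p_value = p, tier = significance_tier(p), pairwise = NULL),
    class = "group_comparison"
  )
}

as_group_list <- function(data, value, group) {
  if (is.list(data) && !is.data.frame(data)) {
    gl <- data
    if (is.null(names(gl))) names(gl) <- paste0("g", seq_along(gl))
  } else {
    v <- dplyr::pull(data, {{ value }})
    g <- dplyr::pull(data, {{ group }})
    keep <- !is.na(v) & !is.na(g)
    gl <- split(v[keep], g[keep], drop = TRUE)
  }
  lapply(gl, function(x) x[!is.na(x)])
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n",
              x$method, x$statistic, x$p_value, x$tier))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Screen feature-outcome correlations
#'
#' Computes the correlation of every feature column against every outcome
#' column, with pairwise-complete deletion, and flags coefficients with
#' `|rho| > 0.7` (strictly) as important. Spearman is the default, matching
#' the package's screening convention; Pearson is also available. Constant
#' columns yield an undefined (missing) coefficient, never an error.
#'
#' @param features Data frame of numeric feature columns (imaging rows of
#'   the screen).
#' @param outcomes Data frame of numeric outcome columns, same row order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param threshold Importance threshold on `|rho|` (default 0.7, strict).
#' @return Tibble with `feature`, `outcome`, `method`, `rho`, `n` (complete
#'   pairs), `important`.
#' @export
correlation_screen <- function(features, outcomes, method = c("spearman", "pearson"),
                               threshold = 0.7) {
  method <- match.arg(method)
  features <- as_tibble(features)
  outcomes <- as_tibble(outcomes)
  if (nrow(features) != nrow(outcomes)) {
    stop_limbperf("features and outcomes must have the same rows.", "limbperf_validation_error")
  }
  grid <- tidyr::expand_grid(feature = names(features), outcome = names(outcomes))
  res <- purrr::pmap_dfr(grid, function(feature, outcome) {
    x <- features[[feature]]
    y <- outcomes[[outcome]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    rho <- if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      NA_real_
    } else {
      cor(x[ok], y[ok], method = method)
    }
    tibble(feature = feature, outcome = outcome, method = method,
           rho = rho, n = n, important = !is.na(rho) & abs(rho) > threshold)
  })
  res
}

#' Reshape a correlation screen into a matrix-style table
#'
#' @param screen Output of [correlation_screen()].
#' @return Tibble with one row per feature and one column per outcome.
#' @export
correlation_matrix <- function(screen) {
  tidyr::pivot_wider(screen[, c("feature", "outcome", "rho")],
                     names_from = "outcome", values_from = "rho")
}
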