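# canonical chemistry feature names, matching the outcome-summary layout
lab_feature_names <- function() {
  an <- c("ALT", "AST", "Creatinine", "BUN", "K+", "LDH", "CK")
  c(paste(an, "Max Isc"), paste(an, "Rpf"))
}

#' Assemble the per-animal feature table for a synthetic cohort
#'
#' Runs every animal through the extraction path — either profile-level
#' (curves sampled and reduced directly; the fast default) or frame-level
#' (frames rendered, the ROI tracked by cross-correlation, and the profile
#' extracted from the images) — then reduces profiles to the 12 imaging
#' features and joins the chemistry features (seven analytes at maximum
#' ischemia and at 30 min post-reperfusion).
#'
#' @param cohort A [generate_cohort()] result.
#' @param source `"profiles"` (default) or `"frames"`.
#' @param noise Noise multiplier passed to the generators.
#' @return Tibble: `animal_id`, `group`, `outcome`, `usable`,
#'   `exclusion_reason`, 12 imaging feature columns, 14 chemistry feature
#'   columns.
#' @export
cohort_features <- function(cohort, source = c("profiles", "frames"), noise = 1) {
  source <- match.arg(source)
  config <- cohort$config
  rows <- purrr::map_dfr(cohort$animals$animal_id, function(aid) {
    if (source == "profiles") {
      prof <- generate_profiles(cohort, aid, noise = noise)
    } else {
      seqs <- generate_imaging_series(cohort, aid, noise = noise)
      h <- config$image_dim[1]; w <- config$image_dim[2]
      r0 <- roi(round(h / 2) - 8, round(w / 2) - 10, 16, 20)
      prof <- list(
        color = extract_profile(seqs$color, track = track_roi(seqs$color, r0)),
        infrared = extract_profile(seqs$infrared,
                                   track = track_roi(seqs$infrared, r0))
      )
    }
    imaging <- build_feature_vector(color = prof$color, infrared = prof$infrared)

    labs <- generate_labs(cohort, aid, noise = noise)
    i <- cohort_row(cohort, aid)
    tl <- group_timeline(cohort$animals$group[i], config)
    lab_at <- function(tp) {
      d <- labs[labs$timepoint_min == tp &
                  labs$analyte %in% c("ALT", "AST", "Creatinine", "BUN", "K+", "LDH", "CK"), ]
      setNames(d$value[match(c("ALT", "AST", "Creatinine", "BUN", "K+", "LDH", "CK"),
                             d$analyte)],
               c("ALT", "AST", "Creatinine", "BUN", "K+", "LDH", "CK"))
    }
    lab_feats <- c(lab_at(tl$release), lab_at(tl$release + 30))
    names(lab_feats) <- lab_feature_names()
    dplyr::bind_cols(tibble(animal_id = aid), imaging, as_tibble(as.list(lab_feats)))
  })
  cohort$animals |>
    dplyr::select("animal_id", "group", "outcome", "usable", "exclusion_reason") |>
    dplyr::left_join(rows, by = "animal_id")
}

#' Summarize metrics by recovery outcome
#'
#' Mean and standard deviation of each metric for the recovered and
#' not-recovered groups, with a Kruskal-Wallis p-value per metric and the
#' usual significance markers (`*` p < 0.05, dagger for p approaching 0.1).
#' If either outcome group is empty the summary is emitted without
#' p-values.
#'
#' @param data Tibble with an `outcome` column (`"recovered"` /
#'   `"not_recovered"`) and numeric metric columns.
#' @param metrics Metric column names; default all numeric columns.
#' @param outcome Outcome column name.
#' @return Tibble: `metric`, `mean_recovered`, `sd_recovered`,
#'   `mean_not_recovered`, `sd_not_recovered`, `p_value`, `marker`.
#' @export
summarize_by_outcome <- function(data, metrics = NULL, outcome = "outcome") {
  metrics <- metrics %||% names(data)[vapply(data, is.numeric, logical(1))]
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  lev <- c("recovered", "not_recovered")
  both <- all(lev %in% d[[outcome]])
  purrr::map_dfr(metrics, function(m) {
    v <- d[[m]]; g <- d[[outcome]]
    ok <- !is.na(v)
    stat <- function(l, f) if (any(ok & g == l)) f(v[ok & g == l]) else NA_real_
    p <- NA_real_
    if (both && sum(ok & g == lev[1]) >= 1 && sum(ok & g == lev[2]) >= 1 && sum(ok) >= 3) {
      p <- kruskal_wallis(list(recovered = v[ok & g == lev[1]],
                               not_recovered = v[ok & g == lev[2]]))$p_value
    }
    tibble(
      metric = m,
      mean_recovered = stat("recovered", mean),
      sd_recovered = stat("recovered", sd),
      mean_not_recovered = stat("not_recovered", mean),
      sd_not_recovered = stat("not_recovered", sd),
      p_value = p,
      marker = significance_tier(p, dagger = TRUE)
    )
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate, extract, feature-build, group statistics,
#' correlation screens, and the three PLSDA experiments (all features,
#' imaging only, non-imaging — each excluding outcome-derived parameters),
#' exactly reproducible from the seed. Optionally writes every artifact to
#' `out_dir` as CSV/JSON together with a manifest.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed driving the whole run.
#' @param out_dir Optional output directory; created if missing.
#' @param feature_sets Subset of `c("all", "imaging_only", "non_imaging")`.
#' @param n_splits,n_iterations Cross-validation settings (defaults 4, 10).
#' @param select_lv Choose 1 vs 2 latent variables per experiment by best
#'   cross-validated AUC (default `TRUE`; otherwise 2 are used).
#' @param source Feature extraction path, `"profiles"` or `"frames"` (see
#'   [cohort_features()]).
#' @return A `limbperf_run` list: `cohort`, `features`, `summary`,
#'   `correlations` (function/pathology and chemistry screens), `models`
#'   (named `plsda_cv` objects), `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir = NULL,
                         feature_sets = c("all", "imaging_only", "non_imaging"),
                         n_splits = 4, n_iterations = 10, select_lv = TRUE,
                         source = "profiles") {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  cohort <- generate_cohort(config, seed)
  features <- cohort_features(cohort, source = source)

  usable <- features[features$usable, , drop = FALSE]
  outcomes_tbl <- cohort$animals[cohort$animals$usable,
                                 c("animal_id", "tarlov_d1", "tarlov_d2", "tarlov_d3",
                                   "tarlov_d7", "drop_foot", "pathology_muscle")]
  summary_tbl <- summarize_by_outcome(
    dplyr::left_join(usable, outcomes_tbl, by = "animal_id"),
    metrics = c(imaging_feature_names(), lab_feature_names(),
                "tarlov_d1", "tarlov_d2", "tarlov_d3", "tarlov_d7",
                "drop_foot", "pathology_muscle")
  )

  img <- usable[, imaging_feature_names()]
  corr_function <- correlation_screen(
    img,
    outcomes_tbl[match(usable$animal_id, outcomes_tbl$animal_id),
                 c("tarlov_d1", "tarlov_d2", "tarlov_d7", "drop_foot",
                   "pathology_muscle")]
  )
  corr_chemistry <- correlation_screen(img, usable[, lab_feature_names()])

  set_features <- list(
    all = c(imaging_feature_names(), lab_feature_names()),
    imaging_only = imaging_feature_names(),
    non_imaging = lab_feature_names()
  )
  models <- purrr::imap(set_features[feature_sets], function(fc, nm) {
    k <- match(nm, names(set_features))
    # structurally missing feature columns (never observed) carry no
    # information; drop them from the model rather than imputing
    observed <- fc[colSums(!is.na(usable[, fc])) > 0]
    cv_seed <- child_seed(seed, k)
    if (select_lv) {
      select_ncomp(usable, features = observed, n_splits = n_splits,
                   n_iterations = n_iterations, seed = cv_seed)
    } else {
      cross_validate(usable, features = observed, ncomp = 2,
                     n_splits = n_splits, n_iterations = n_iterations,
                     seed = cv_seed)
    }
  })

  gen_excl <- cohort$animals[cohort$animals$excluded,
                             c("animal_id", "exclusion_reason")]
  names(gen_excl) <- c("animal_id", "reason")
  model_excl <- purrr::imap_dfr(models, function(m, nm) {
    if (nrow(m$exclusion_log)) dplyr::mutate(m$exclusion_log[, c("animal_id", "reason")],
                                             feature_set = nm)
    else tibble(animal_id = character(), reason = character(), feature_set = character())
  })
  exclusions <- dplyr::bind_rows(
    dplyr::mutate(gen_excl, feature_set = "cohort"), model_excl
  )

  manifest <- list(
    package = "limbperf",
    version = as.character(utils::packageVersion("limbperf")),
    seed = seed,
    n_generated = nrow(cohort$animals),
    n_usable = sum(cohort$animals$usable),
    n_excluded = sum(cohort$animals$excluded),
    feature_sets = feature_sets,
    cv = list(n_splits = n_splits, n_iterations = n_iterations,
              select_lv = select_lv),
    source = source,
    models = purrr::map(models, model_report)
  )

  run <- structure(
    list(cohort = cohort, features = features, summary = summary_tbl,
         correlations = list(function_pathology = corr_function,
                             chemistry = corr_chemistry),
         models = models, exclusions = exclusions, manifest = manifest),
    class = "limbperf_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

model_report <- function(m) {
  list(
    ncomp = m$settings$ncomp,
    n = nrow(m$model$Tscores),
    cv = list(sensitivity = m$cv$sensitivity, specificity = m$cv$specificity,
              auc = m$cv$auc),
    pooled = c(as.list(m$pooled$confusion), list(auc = m$pooled$auc)),
    calibration = c(as.list(m$calibration$confusion), list(auc = m$calibration$auc))
  )
}

#' @export
print.limbperf_run <- function(x, ...) {
  cat(sprintf("<limbperf_run> seed %s: %d animals (%d usable)\n",
              format(x$manifest$seed), x$manifest$n_generated, x$manifest$n_usable))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-13s %d LV  CV sens %5.1f%%  spec %5.1f%%  AUC %.3f\n",
                nm, m$settings$ncomp, m$cv$sensitivity, m$cv$specificity, m$cv$auc))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Deterministic CSV/JSON serialization of a [run_pipeline()] result:
#' feature table, outcome summary, correlation screens, per-model reports
#' and ROC points, exclusion log, and a manifest. Re-running with the same
#' configuration and seed reproduces every file byte for byte.
#'
#' @param run A `limbperf_run`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) readr::write_csv(d, file.path(out_dir, f))
  w(run$features, "features.csv")
  w(run$summary, "summary_by_outcome.csv")
  w(correlation_matrix(run$correlations$function_pathology), "correlation_function.csv")
  w(correlation_matrix(run$correlations$chemistry), "correlation_chemistry.csv")
  w(run$exclusions, "exclusions.csv")
  for (nm in names(run$models)) {
    w(run$models[[nm]]$pooled$roc, sprintf("roc_cv_%s.csv", nm))
    w(run$models[[nm]]$calibration$roc, sprintf("roc_calibration_%s.csv", nm))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
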