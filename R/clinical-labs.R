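#' Convert blood urea nitrogen to serum urea
#'
#' BUN in mg/dL measures the nitrogen bound in urea. Each urea molecule
#' carries two nitrogen atoms of 14.01 g/mol, so
#' `urea (mmol/L) = BUN (mg/dL) * 10 / 28.02` — the conventional 0.357
#' factor. Strictly increasing and invertible.
#'
#' @param bun Non-negative BUN values, mg/dL.
#' @return Serum urea, mmol/L.
#' @export
bun_to_urea <- function(bun) {
  if (any(bun < 0, na.rm = TRUE)) {
    stop_limbperf("BUN cannot be negative.", "limbperf_validation_error")
  }
  bun * 10 / 28.02
}

#' Normalize a serum analyte to urea content
#'
#' Expresses an analyte activity per mmol of serum urea (U/mmol), which
#' guards trend interpretation against hydration status. Bicarbonate
#' (reported as CO2) is deliberately refused: it is the one chemistry
#' left unnormalized.
#'
#' @param value Analyte activity (U/L) or concentration.
#' @param urea Serum urea, mmol/L; must be positive.
#' @param analyte Optional analyte name, checked against the CO2 exception.
#' @return `value / urea`, in U/mmol.
#' @export
normalize_to_urea <- function(value, urea, analyte = NULL) {
  if (!is.null(analyte) &&
      tolower(gsub("[^a-z0-9]", "", tolower(analyte))) %in% c("co2", "bicarbonate", "hco3")) {
    stop_limbperf("CO2/bicarbonate is not normalized to urea.", "limbperf_validation_error")
  }
  if (any(!is.na(urea) & urea <= 0)) {
    stop_limbperf("Serum urea must be positive for normalization.", "limbperf_validation_error")
  }
  value / urea
}

#' Label an animal as fully recovered
#'
#' Full recovery of locomotion means a modified Tarlov score of 5 (normal
#' gait) at day 7. A missing day-7 score yields a missing label, and such
#' animals are excluded from the outcome models downstream. Drop-foot is
#' intentionally not part of the definition: residual neuropathy can
#' coexist with a normal gait score.
#'
#' @param tarlov_d7 Integer vector of day-7 Tarlov scores (0-5).
#' @return Logical vector: `TRUE` = recovered, `NA` when the score is
#'   missing.
#' @export
recovered_fully <- function(tarlov_d7) {
  bad <- !is.na(tarlov_d7) & (tarlov_d7 < 0 | tarlov_d7 > 5 | tarlov_d7 != floor(tarlov_d7))
  if (any(bad)) {
    stop_limbperf("Tarlov scores must be integers in 0..5.", "limbperf_validation_error")
  }
  ifelse(is.na(tarlov_d7), NA, tarlov_d7 == 5)
}

#' Total histopathology score
#'
#' Sum of the five 0-5 subscores graded per tissue section: edema,
#' non-suppurative inflammation, degeneration, necrosis, and regeneration.
#' A total of 25 is the highest level of injury; 0 is uninjured tissue.
#'
#' @param edema,inflammation,degeneration,necrosis,regeneration Integer
#'   subscores, each in 0..5.
#' @return Integer total in 0..25.
#' @export
pathology_total <- function(edema, inflammation, degeneration, necrosis, regeneration) {
  sub <- cbind(edema, inflammation, degeneration, necrosis, regeneration)
  bad <- !is.na(sub) & (sub < 0 | sub > 5 | sub != floor(sub))
  if (any(bad)) {
    stop_limbperf("Pathology subscores must be integers in 0..5.", "limbperf_validation_error")
  }
  as.integer(rowSums(sub))
}

#' Long-format chemistry table with urea-normalized analytes
#'
#' Takes a long chemistry table (`animal_id`, `timepoint_min`, `analyte`,
#' `value`), converts the BUN rows to serum urea, and appends a
#' `value_per_urea` column giving each analyte normalized to the same
#' draw's urea — except CO2/bicarbonate, which stays unnormalized.
#'
#' @param draws Long tibble of chemistry draws.
#' @return Input tibble with an added `value_per_urea` column.
#' @export
normalize_chemistry <- function(draws) {
  stopifnot(all(c("animal_id", "timepoint_min", "analyte", "value") %in% names(draws)))
  urea <- draws |>
    dplyr::filter(.data$analyte == "BUN") |>
    dplyr::mutate(urea = bun_to_urea(.data$value)) |>
    dplyr::select("animal_id", "timepoint_min", "urea")
  draws |>
    dplyr::left_join(urea, by = c("animal_id", "timepoint_min")) |>
    dplyr::mutate(
      value_per_urea = dplyr::if_else(
        .data$analyte %in% c("CO2", "BUN") | is.na(.data$urea) | .data$urea <= 0,
        NA_real_,
        .data$value / .data$urea
      )
    ) |>
    dplyr::select(-"urea")
}
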