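#' Day validity by valid-epoch count
#'
#' A recording day is valid when it contains at least `min_valid_epochs`
#' valid 5-min epochs; the boundary counts as valid (the exclusion rule is
#' strictly "fewer than"). The default threshold is 100; 200 is the
#' conventional sensitivity threshold.
#'
#' @param n_valid_epochs Count of valid epochs in a day (vectorized).
#' @param min_valid_epochs Validity threshold.
#' @return Logical vector: `TRUE` for valid days.
#' @export
day_validity <- function(n_valid_epochs, min_valid_epochs = 100L) {
  n_valid_epochs >= min_valid_epochs
}

# per (subject, day): number of valid epochs and day validity
day_table <- function(epochs, min_valid_epochs = 100L) {
  epochs |>
    dplyr::group_by(.data$subject_id, .data$day_index) |>
    dplyr::summarise(n_valid_epochs = sum(.data$valid), .groups = "drop") |>
    dplyr::mutate(day_valid = day_validity(.data$n_valid_epochs,
                                           min_valid_epochs))
}

#' Average valid days into one 24-hour profile per subject
#'
#' Applies the day-validity rule, then averages Ln(HF) at each time-of-day
#' bin separately across the surviving days. Bins observed on no valid day
#' are missing (not zero, not imputed). Subjects with no valid day are
#' excluded (listed in the `excluded` attribute).
#'
#' @param epochs Epoch tibble with `subject_id`, `day_index`, `bin`,
#'   `ln_hf`, `valid`.
#' @param min_valid_epochs Day-validity threshold (default 100).
#' @return Profile tibble (`subject_id`, `bin`, `y`, `n_days_contributing`)
#'   plus per-subject attribute columns via `attr(,"subjects")`
#'   (`n_recorded_days`, `n_valid_days`) and `attr(,"excluded")`.
#' @export
build_profiles <- function(epochs, min_valid_epochs = 100L) {
  days <- day_table(epochs, min_valid_epochs)
  subjects <- days |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_recorded_days = dplyr::n(),
                     n_valid_days = sum(.data$day_valid), .groups = "drop")
  excluded <- subjects$subject_id[subjects$n_valid_days == 0]
  valid_days <- days |> dplyr::filter(.data$day_valid)
  prof <- epochs |>
    dplyr::filter(.data$valid) |>
    dplyr::inner_join(valid_days[, c("subject_id", "day_index")],
                      by = c("subject_id", "day_index")) |>
    dplyr::group_by(.data$subject_id, .data$bin) |>
    dplyr::summarise(y = mean(.data$ln_hf),
                     n_days_contributing = dplyr::n(), .groups = "drop")
  attr(prof, "subjects") <- subjects
  attr(prof, "excluded") <- excluded
  prof
}

#' @rdname build_profiles
#' @param subject_id Single subject to profile.
#' @export
build_profile <- function(epochs, subject_id, min_valid_epochs = 100L) {
  build_profiles(epochs[epochs$subject_id == subject_id, ], min_valid_epochs)
}

#' Exclusion-flow accounting for a cohort
#'
#' Per-subject counts of recorded and valid days with the applicable
#' exclusion reason, mirroring a sample-selection flowchart: subjects whose
#' every day falls below the valid-epoch threshold are excluded.
#'
#' @inheritParams build_profiles
#' @return Tibble with `subject_id`, `n_recorded_days`, `n_valid_days`,
#'   `excluded`, `reason`.
#' @export
exclusion_report <- function(epochs, min_valid_epochs = 100L) {
  days <- day_table(epochs, min_valid_epochs)
  days |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_recorded_days = dplyr::n(),
                     n_valid_days = sum(.data$day_valid), .groups = "drop") |>
    dplyr::mutate(
      excluded = .data$n_valid_days == 0,
      reason = ifelse(.data$excluded,
                      sprintf("fewer than %d valid 5-min epochs within each day",
                              min_valid_epochs), NA_character_))
}

#' Wide profile matrix (subjects x 288 bins)
#'
#' @param profiles Output of [build_profiles()].
#' @return Numeric matrix, rows named by subject, `NA` for missing bins.
#' @export
profile_matrix <- function(profiles) {
  ids <- unique(profiles$subject_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = N_BINS,
              dimnames = list(ids, NULL))
  m[cbind(match(profiles$subject_id, ids), profiles$bin + 1L)] <- profiles$y
  m
}
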