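#' Preprocess an RR recording into HF epochs
#'
#' Chains cleaning ([flag_and_interpolate()]), clock-aligned segmentation
#' ([segment_epochs()]), and the spectral pass ([compute_epoch_hf()]).
#'
#' @param recording RR series tibble.
#' @param spectral A [spectral_config()].
#' @param deviation_threshold,window,max_run Cleaning parameters, see
#'   [flag_and_interpolate()].
#' @param max_interp_frac Epoch exclusion threshold.
#' @return Epoch tibble with `hf_ms2`, `ln_hf`, `valid`.
#' @export
preprocess_rr <- function(recording, spectral = spectral_config(),
                          deviation_threshold = 0.2, window = 5L,
                          max_run = 3L, max_interp_frac = 0.2) {
  cleaned <- flag_and_interpolate(recording, deviation_threshold, window,
                                  max_run)
  shells <- segment_epochs(cleaned)
  compute_epoch_hf(shells, spectral, max_interp_frac)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a cohort, generates recordings (signal-level RR path or the
#' fast direct epoch path), preprocesses them into valid epochs, applies
#' day-validity filtering, builds per-subject 24-h profiles, classifies
#' cognitive status from simulated neuropsychological scores, fits the
#' function-on-scalar model, and assembles the cohort summary.
#'
#' @param config A [generator_config()].
#' @param path `"rr"` for the full signal path (RR synthesis, artifact
#'   cleaning, interval spectra) or `"direct"` for epoch-level generation.
#' @param min_valid_epochs Day-validity threshold (100; use 200 for the
#'   sensitivity analysis).
#' @param fit_model Fit the function-on-scalar model? (Skipping saves time
#'   when only the preprocessing stages are of interest.)
#' @param model Covariate set for the fit, see [build_design()].
#' @param spectral A [spectral_config()] (RR path only).
#' @return List: `covariates`, `truth`, `scores`, `classification`,
#'   `epochs`, `profiles`, `exclusions`, `person_means`, `summary`, and
#'   (optionally) `fit`.
#' @export
run_pipeline <- function(config = generator_config(),
                         path = c("rr", "direct"),
                         min_valid_epochs = 100L, fit_model = TRUE,
                         model = "primary", spectral = spectral_config()) {
  path <- match.arg(path)
  sim <- simulate_cohort(config)

  if (path == "direct") {
    epochs <- simulate_epochs_direct(sim, wear = TRUE)
  } else {
    per_subject <- lapply(sim$covariates$subject_id, function(id) {
      rec <- simulate_subject_recording(sim, id)
      if (nrow(rec) == 0) return(NULL)
      preprocess_rr(rec, spectral)
    })
    epochs <- dplyr::bind_rows(per_subject)
  }

  exclusions <- exclusion_report(epochs, min_valid_epochs)
  profiles <- build_profiles(epochs, min_valid_epochs)
  person_means <- person_level_means(epochs, min_valid_epochs)

  scores <- simulate_neuropsych(sim)
  classification <- classify_cohort(scores)

  covariates <- dplyr::left_join(
    sim$covariates |> dplyr::select(-"mci"),
    classification[, c("subject_id", "mci")], by = "subject_id")

  summary <- summarize_cohort(
    covariates, person_means,
    exclusions[, c("subject_id", "n_recorded_days", "n_valid_days")])

  out <- list(covariates = covariates, truth = sim$truth, scores = scores,
              classification = classification, epochs = epochs,
              profiles = profiles, exclusions = exclusions,
              person_means = person_means, summary = summary)
  if (fit_model) {
    design <- build_design(profiles, covariates, model = model)
    out$fit <- fosr_fit(design)
  }
  out
}

#' Read and write the pipeline's file formats
#'
#' Plain-CSV readers/writers for RR series, epoch tables, covariates,
#' profiles, and neuropsychological scores, plus JSON serialization of fit
#' results and JSON/YAML run configuration.
#'
#' @param path File path.
#' @param x Object to write.
#' @name hrv_io
NULL

#' @rdname hrv_io
#' @export
read_rr_csv <- function(path) {
  df <- tibble::as_tibble(data.table::fread(path))
  need <- c("subject_id", "day_index", "beat_time_s", "rr_ms")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("RR CSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"interpolated" %in% names(df)) df$interpolated <- FALSE
  df$interpolated <- as.logical(df$interpolated)
  if (any(df$rr_ms <= 0)) stop("rr_ms must be positive", call. = FALSE)
  df
}

#' @rdname hrv_io
#' @export
write_rr_csv <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}

#' @rdname hrv_io
#' @export
read_table_csv <- function(path) tibble::as_tibble(read.csv(path))

#' @rdname hrv_io
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hrv_io
#' @export
write_fit_json <- function(x, path) {
  stopifnot(inherits(x, "hrv_fosr_fit"))
  ci <- pointwise_ci(x)
  out <- list(
    model = x$design$model, target = x$design$target,
    n_obs = x$n_obs, n_subjects = length(x$subject_intercepts),
    sigma_b = x$sigma_b, sigma_eps = x$sigma_eps,
    lambda = as.list(x$lambda), edf = as.list(x$edf), reml = x$reml,
    convergence = x$convergence,
    curves = split(ci[, c("bin", "hour", "estimate", "se", "lower", "upper")],
                   ci$coefficient))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hrv_io
#' @export
fit_tidy <- function(x) {
  stopifnot(inherits(x, "hrv_fosr_fit"))
  pointwise_ci(x)
}

#' @rdname hrv_io
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg),
                        c("n_subjects", "prop_mci", "sigma_b", "sigma_eps",
                          "rr_base_ms", "rsa_freq_hz", "n_days",
                          "artifact_rate", "seed"))]
  if (!is.null(cfg$mean_profile))
    args$mean_profile <- do.call(cosinor_curve, cfg$mean_profile)
  if (!is.null(cfg$mci_effect_profile))
    args$mci_effect_profile <- do.call(raised_cosine_dip,
                                       cfg$mci_effect_profile)
  if (!is.null(cfg$covariate_effects))
    args$covariate_effects <- cfg$covariate_effects
  if (!is.null(cfg$wear_model)) {
    wm <- list(day_dropout = cfg$wear_model$day_dropout %||% 0.175,
               retention = cfg$wear_model$retention %||% default_retention())
    args$wear_model <- wm
  }
  do.call(generator_config, args)
}
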