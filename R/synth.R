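#' Configuration for the synthetic cohort generator
#'
#' Defines the data-generating conditions for a simulated ambulatory-HRV
#' study: cohort composition, the true coefficient curves of the
#' function-on-scalar model, variance components, the RR-interval signal
#' model, and the wear/artifact missingness model. Defaults are calibrated so
#' that the full pipeline reproduces the margins of the motivating cohort:
#' 81 subjects with ~25% MCI, 8 recorded days of which ~6.6 survive the
#' 100-valid-epoch day rule, and person-level mean Ln(HF-HRV) ~4.5 with
#' between-person SD ~0.8 ln ms^2.
#'
#' @param n_subjects Number of subjects.
#' @param prop_mci Proportion classified MCI; the realized count is
#'   `round(n_subjects * prop_mci)`.
#' @param mean_profile Curve spec for the functional intercept (expected
#'   24-h Ln(HF-HRV) profile of the reference subject), see [cosinor_curve()].
#' @param mci_effect_profile Curve spec for the MCI coefficient curve;
#'   default a raised-cosine nocturnal dip of depth 0.6 ln ms^2 centered at
#'   midnight spanning 19:00-07:00, see [raised_cosine_dip()].
#' @param covariate_effects Named list of constants or curve specs for the
#'   remaining coefficient curves (age and education per year, centered at
#'   78.3 and 14.9 years; female; Black and other ethnicity vs non-Hispanic
#'   White; depression, diabetes, hypertension flags).
#' @param sigma_b SD of the subject random intercept (ln ms^2).
#' @param sigma_eps SD of the epoch-level white noise (ln ms^2).
#' @param rr_base_ms Mean RR interval of the simulated tachogram (ms).
#' @param rsa_freq_hz Respiratory (HF) modulation frequency; must lie inside
#'   the 0.15-0.40 Hz analysis band.
#' @param n_days Recorded days per subject.
#' @param wear_model List with `day_dropout` (probability a whole recorded
#'   day is lost) and `retention` (per-epoch wear probability: a single
#'   number, a 288-vector, or a curve spec evaluated over the clock).
#' @param artifact_rate Fraction of beats corrupted by artifacts.
#' @param seed Integer seed; identical configs give identical output.
#' @return A validated `hrv_generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 12, seed = 7)
#' sim <- simulate_cohort(cfg)
#' head(sim$covariates)
generator_config <- function(n_subjects = 81,
                             prop_mci = 20 / 81,
                             mean_profile = cosinor_curve(4.5, 0.7, 3),
                             mci_effect_profile = raised_cosine_dip(0.6, 0, 6),
                             covariate_effects = list(
                               age = -0.02, female = 0.15,
                               black = -0.10, other = -0.10,
                               education = 0.01,
                               depression = 0, diabetes = 0, hypertension = 0),
                             sigma_b = 0.78,
                             sigma_eps = 1.0,
                             rr_base_ms = 800,
                             rsa_freq_hz = 0.25,
                             n_days = 8,
                             wear_model = list(day_dropout = 0.175,
                                               retention = default_retention()),
                             artifact_rate = 0.02,
                             seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_config("n_subjects", "must be a positive count")
  if (!is.numeric(prop_mci) || prop_mci < 0 || prop_mci > 1)
    stop_config("prop_mci", "must lie in [0, 1]")
  if (!is.numeric(sigma_b) || sigma_b < 0)
    stop_config("sigma_b", "must be >= 0")
  if (!is.numeric(sigma_eps) || sigma_eps < 0)
    stop_config("sigma_eps", "must be >= 0")
  if (rsa_freq_hz < 0.15 || rsa_freq_hz > 0.40)
    stop_config("rsa_freq_hz", "must lie in [0.15, 0.40] Hz")
  if (rr_base_ms <= 0) stop_config("rr_base_ms", "must be positive")
  if (n_days < 1) stop_config("n_days", "must be a positive count")
  if (!is.list(wear_model) || is.null(wear_model$day_dropout) ||
      is.null(wear_model$retention))
    stop_config("wear_model", "needs day_dropout and retention")
  if (wear_model$day_dropout < 0 || wear_model$day_dropout > 1)
    stop_config("wear_model", "day_dropout must lie in [0, 1]")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop_config("artifact_rate", "must lie in [0, 1]")
  defaults <- list(age = 0, female = 0, black = 0, other = 0, education = 0,
                   depression = 0, diabetes = 0, hypertension = 0)
  unknown <- setdiff(names(covariate_effects), names(defaults))
  if (length(unknown) > 0)
    stop_config("covariate_effects", paste("unknown covariate:", unknown[1]))
  defaults[names(covariate_effects)] <- covariate_effects

  structure(list(
    n_subjects = as.integer(n_subjects), prop_mci = prop_mci,
    mean_profile = mean_profile, mci_effect_profile = mci_effect_profile,
    covariate_effects = defaults, sigma_b = sigma_b, sigma_eps = sigma_eps,
    rr_base_ms = rr_base_ms, rsa_freq_hz = rsa_freq_hz,
    n_days = as.integer(n_days), wear_model = wear_model,
    artifact_rate = artifact_rate, seed = as.integer(seed),
    age_ref = 78.3, edu_ref = 14.9
  ), class = "hrv_generator_config")
}

#' @rdname generator_config
#' @details `default_retention()` returns the default per-epoch wear
#'   probability over the clock: high overnight with a mild mid-afternoon dip
#'   (device off-wrist periods), averaging ~0.90.
#' @export
default_retention <- function() {
  h <- bin_to_hour(0:287)
  0.93 - 0.09 * exp(-((h - 14) / 4)^2)
}

eval_retention <- function(retention) {
  r <- if (inherits(retention, "hrv_curve")) eval_curve(retention)
       else if (length(retention) == 1L) rep(retention, N_BINS)
       else retention
  stopifnot(length(r) == N_BINS, all(r >= 0), all(r <= 1))
  r
}

# covariates entering the data-generating model, in truth-curve order
TRUTH_COVARIATES <- c("mci", "age_c", "female", "black", "other",
                      "education_c", "depression", "diabetes", "hypertension")

#' Simulate a cohort and its ground-truth model parameters
#'
#' Draws a covariate table matching the marginal distributions of the
#' motivating study (age truncated-normal 78.3 (5.2) with minimum 70; 81.5%
#' female; ethnicity 38.3/43.2/18.5% non-Hispanic White/Black/other;
#' education 14.9 (3.3) years; comorbidity flags) together with the true
#' coefficient curves on the 288-bin grid and per-subject random intercepts.
#'
#' @param config A [generator_config()].
#' @return A list with `covariates` (tibble, one row per subject) and
#'   `truth` (class `hrv_truth`: `beta_curves` 288 x 9 matrix,
#'   `subject_intercepts`, design matrix `x`, and the config echo).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "hrv_generator_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_subjects

  age <- qnorm(runif(n, pnorm(70, 78.3, 5.2), 1), 78.3, 5.2)
  sex <- ifelse(runif(n) < 0.815, "female", "male")
  ethnicity <- sample(c("nh_white", "nh_black", "other"), n, replace = TRUE,
                      prob = c(0.383, 0.432, 0.185))
  education <- round(pmin(pmax(rnorm(n, 14.9, 3.3), 6), 22))
  n_mci <- round(n * config$prop_mci)
  mci <- integer(n)
  if (n_mci > 0) mci[sample.int(n, n_mci)] <- 1L
  covariates <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, sex = sex, ethnicity = ethnicity, education = education,
    mci = mci,
    depression = rbinom(n, 1, 0.15),
    diabetes = rbinom(n, 1, 0.185),
    hypertension = rbinom(n, 1, 0.679))

  x <- cbind(
    mci = covariates$mci,
    age_c = covariates$age - config$age_ref,
    female = as.integer(covariates$sex == "female"),
    black = as.integer(covariates$ethnicity == "nh_black"),
    other = as.integer(covariates$ethnicity == "other"),
    education_c = covariates$education - config$edu_ref,
    depression = covariates$depression,
    diabetes = covariates$diabetes,
    hypertension = covariates$hypertension)
  rownames(x) <- covariates$subject_id

  eff <- config$covariate_effects
  beta_curves <- cbind(
    intercept = eval_curve(config$mean_profile),
    mci = eval_curve(config$mci_effect_profile),
    age_c = eval_curve(eff$age),
    female = eval_curve(eff$female),
    black = eval_curve(eff$black),
    other = eval_curve(eff$other),
    education_c = eval_curve(eff$education),
    depression = eval_curve(eff$depression),
    diabetes = eval_curve(eff$diabetes),
    hypertension = eval_curve(eff$hypertension))

  truth <- structure(list(
    beta_curves = beta_curves,
    subject_intercepts = stats::setNames(rnorm(n, 0, config$sigma_b),
                                         covariates$subject_id),
    x = x, config = config), class = "hrv_truth")
  list(covariates = covariates, truth = truth)
}

#' Noise-free and noisy epoch-level Ln(HF-HRV) under the generating model
#'
#' Evaluates `sum_k beta_k(bin) x_ik + b_i` for one subject at given bins,
#' optionally adding epoch-level Gaussian noise with SD `sigma_eps`.
#'
#' @param truth A `hrv_truth` object from [simulate_cohort()].
#' @param subject_id Subject identifier present in the cohort.
#' @param bin Bin indices in `0:287` (vectorized).
#' @param noisy Add `N(0, sigma_eps^2)` epoch noise?
#' @return Numeric vector of Ln(HF-HRV) values (ln ms^2).
#' @export
epoch_lnhf_truth <- function(truth, subject_id, bin, noisy = FALSE) {
  stopifnot(inherits(truth, "hrv_truth"), all(bin >= 0L), all(bin <= 287L))
  if (!subject_id %in% rownames(truth$x))
    stop("unknown subject: ", subject_id, call. = FALSE)
  mu <- truth$beta_curves[bin + 1L, "intercept"] +
    drop(truth$beta_curves[bin + 1L, TRUTH_COVARIATES, drop = FALSE] %*%
           truth$x[subject_id, TRUTH_COVARIATES]) +
    truth$subject_intercepts[[subject_id]]
  if (noisy) mu <- mu + rnorm(length(mu), 0, truth$config$sigma_eps)
  unname(mu)
}

# subject x bin matrix of noise-free means (288 x n)
truth_mean_matrix <- function(truth) {
  truth$beta_curves[, "intercept"] +
    truth$beta_curves[, TRUTH_COVARIATES, drop = FALSE] %*%
      t(truth$x[, TRUTH_COVARIATES, drop = FALSE]) +
    matrix(truth$subject_intercepts, nrow = N_BINS,
           ncol = nrow(truth$x), byrow = TRUE)
}

# per-day wear draws for one subject: NULL if the day is dropped, otherwise
# the retained bin indices (0-based)
draw_wear_days <- function(config, full_wear = FALSE) {
  if (full_wear) return(replicate(config$n_days, 0:287, simplify = FALSE))
  ret <- eval_retention(config$wear_model$retention)
  lapply(seq_len(config$n_days), function(d) {
    if (runif(1) < config$wear_model$day_dropout) return(NULL)
    (0:287)[runif(N_BINS) < ret]
  })
}

#' Simulate epoch-level Ln(HF-HRV) directly (no RR synthesis)
#'
#' The fast generation path: epoch values are drawn directly from the
#' generating model, bypassing RR-interval synthesis and spectral
#' estimation. Used for model-recovery studies where signal-processing error
#' is irrelevant.
#'
#' @param sim Output of [simulate_cohort()].
#' @param wear Apply the wear/dropout model? With `FALSE` every subject has
#'   complete 288-epoch days.
#' @return Epoch tibble (`subject_id`, `day_index`, `bin`, `ln_hf`,
#'   `frac_interpolated`, `valid`).
#' @export
simulate_epochs_direct <- function(sim, wear = FALSE) {
  config <- sim$truth$config
  set.seed(derive_seed(config$seed, 2L))
  mu <- truth_mean_matrix(sim$truth)
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    days <- draw_wear_days(config, full_wear = !wear)
    rows <- lapply(seq_along(days), function(d) {
      bins <- days[[d]]
      if (is.null(bins) || length(bins) == 0) return(NULL)
      tibble::tibble(day_index = d, bin = bins,
                     ln_hf = mu[bins + 1L, i] +
                       rnorm(length(bins), 0, config$sigma_eps))
    })
    out[[i]] <- dplyr::bind_rows(rows)
    out[[i]]$subject_id <- sim$covariates$subject_id[i]
  }
  res <- dplyr::bind_rows(out)
  res$frac_interpolated <- 0
  res$valid <- TRUE
  dplyr::select(res, "subject_id", "day_index", "bin", "ln_hf",
                "frac_interpolated", "valid")
}

#' Simulate one 5-minute RR-interval segment with a target HF power
#'
#' Produces a sinusoidally modulated tachogram whose HF band power equals
#' `exp(target_lnhf)`: `rr = rr_base_ms + A sin(2 pi f tau)` with
#' `A = sqrt(2 exp(target_lnhf))` (a sinusoid of amplitude A carries power
#' A^2/2).
#'
#' @param target_lnhf Target Ln(HF) in ln ms^2 (finite).
#' @param config A [generator_config()] (uses `rr_base_ms`, `rsa_freq_hz`).
#' @param t0_s Clock time (s since midnight) of the epoch start.
#' @return Tibble with `beat_time_s` and `rr_ms`.
#' @export
#' @examples
#' seg <- simulate_rr_epoch(log(450), generator_config())
#' nrow(seg)  # ~375 beats in 300 s at 800 ms
simulate_rr_epoch <- function(target_lnhf, config, t0_s = 0) {
  stopifnot(is.finite(target_lnhf))
  A <- sqrt(2 * exp(target_lnhf))
  if (A >= config$rr_base_ms)
    stop("modulation amplitude ", round(A), " ms >= mean RR ",
         config$rr_base_ms, " ms: non-physiological target power",
         call. = FALSE)
  beats <- simulate_rr_epochs_cpp(t0_s, A, config$rr_base_ms,
                                  config$rsa_freq_hz, BIN_SECONDS)
  tibble::tibble(beat_time_s = beats$beat_time_s, rr_ms = beats$rr_ms)
}

# corrupt a fraction of beats: multiply the interval by a factor far enough
# from 1 that the deviation from the local median exceeds 20%
corrupt_beats <- function(rr_ms, artifact_rate) {
  n <- length(rr_ms)
  hit <- runif(n) < artifact_rate
  if (any(hit)) {
    factor <- sample(c(0.55, 1.6), sum(hit), replace = TRUE)
    rr_ms[hit] <- rr_ms[hit] * factor
  }
  list(rr_ms = rr_ms, corrupted = hit)
}

#' Simulate a full multi-day RR recording for one subject
#'
#' The signal-level generation path: wear/dropout draws select retained
#' epochs, each retained epoch gets a target Ln(HF) from the generating model
#' (plus epoch noise), a modulated tachogram is synthesized per epoch, and a
#' fraction of beats is corrupted by artifacts.
#'
#' @param sim Output of [simulate_cohort()].
#' @param subject_id Subject to simulate.
#' @param full_wear Disable the wear/dropout model?
#' @param seed Optional seed override (defaults to a subject-specific seed
#'   derived from the config seed).
#' @return RR series tibble (`subject_id`, `day_index`, `beat_time_s`,
#'   `rr_ms`, `interpolated`) spanning the retained epochs.
#' @export
simulate_subject_recording <- function(sim, subject_id, full_wear = FALSE,
                                       seed = NULL) {
  config <- sim$truth$config
  i <- match(subject_id, sim$covariates$subject_id)
  if (is.na(i)) stop("unknown subject: ", subject_id, call. = FALSE)
  set.seed(seed %||% derive_seed(config$seed, 100L + i))

  mu <- truth_mean_matrix(sim$truth)[, i]
  days <- draw_wear_days(config, full_wear = full_wear)
  per_day <- lapply(seq_along(days), function(d) {
    bins <- days[[d]]
    if (is.null(bins) || length(bins) == 0) return(NULL)
    target <- mu[bins + 1L] + rnorm(length(bins), 0, config$sigma_eps)
    A <- sqrt(2 * exp(target))
    A <- pmin(A, 0.95 * config$rr_base_ms)  # guard extreme noise draws
    beats <- simulate_rr_epochs_cpp(bins * BIN_SECONDS, A, config$rr_base_ms,
                                    config$rsa_freq_hz, BIN_SECONDS)
    # artifacts corrupt the measured interval value; detector timestamps are
    # left as-is (the value/time inconsistency is what flagging detects)
    cor <- corrupt_beats(beats$rr_ms, config$artifact_rate)
    tibble::tibble(day_index = d, beat_time_s = beats$beat_time_s,
                   rr_ms = cor$rr_ms)
  })
  res <- dplyr::bind_rows(per_day)
  if (nrow(res) == 0)
    return(tibble::tibble(subject_id = character(), day_index = integer(),
                          beat_time_s = numeric(), rr_ms = numeric(),
                          interpolated = logical()))
  res$subject_id <- subject_id
  res$interpolated <- FALSE
  dplyr::select(res, "subject_id", "day_index", "beat_time_s", "rr_ms",
                "interpolated")
}

#' Apply the wear/dropout and artifact model to an existing recording
#'
#' Drops whole days with probability `day_dropout`, drops epochs by the
#' retention curve, and corrupts a fraction `artifact_rate` of the remaining
#' beats so that their intervals deviate by more than 20% from the local
#' median (detectable by [flag_and_interpolate()]).
#'
#' @param recording RR series tibble for one or more subjects.
#' @param config A [generator_config()].
#' @param seed Seed for the retention and corruption draws.
#' @return The thinned, corrupted recording.
#' @export
apply_wear_and_artifacts <- function(recording, config, seed = config$seed) {
  set.seed(derive_seed(seed, 3L))
  ret <- eval_retention(config$wear_model$retention)
  out <- recording |>
    dplyr::group_by(.data$subject_id, .data$day_index) |>
    dplyr::group_modify(function(df, key) {
      if (runif(1) < config$wear_model$day_dropout) return(df[0, ])
      bin <- pmin(pmax(floor(df$beat_time_s / BIN_SECONDS), 0), N_BINS - 1)
      keep_bin <- runif(N_BINS) < ret
      df <- df[keep_bin[bin + 1L], ]
      if (nrow(df) == 0) return(df)
      cor <- corrupt_beats(df$rr_ms, config$artifact_rate)
      df$rr_ms <- cor$rr_ms
      df
    }) |>
    dplyr::ungroup()
  out
}

#' Simulate neuropsychological z-scores consistent with assigned MCI status
#'
#' Draws age/sex/education-adjusted z-scores for the 10-instrument battery
#' (5 domains x 2 measures) plus the Lawton-Brody dependency count such that
#' the Jak/Bondi classifier reproduces each subject's assigned status
#' exactly. MCI subjects are realized through a two-test impaired domain
#' (rule 1), a three-domain single-impairment pattern (rule 2), or
#' occasionally full instrumental-activity dependence (rule 3).
#'
#' @param sim Output of [simulate_cohort()].
#' @return Tibble with `subject_id`, the 10 instrument z-score columns, and
#'   `lawton_brody`.
#' @export
simulate_neuropsych <- function(sim) {
  config <- sim$truth$config
  set.seed(derive_seed(config$seed, 4L))
  n <- nrow(sim$covariates)
  draw_one <- function(is_mci) {
    for (attempt in 1:200) {
      z <- rnorm(10, 0.1, 0.7)
      lawton <- 0L
      if (is_mci) {
        style <- sample(c("rule1", "rule2", "rule3"), 1,
                        prob = c(0.6, 0.3, 0.1))
        z <- rnorm(10, -0.3, 0.6)
        if (style == "rule1") {
          dom <- sample.int(5, 1)
          z[2 * dom - 1:0] <- -1.05 - abs(rnorm(2, 0.4, 0.25))
        } else if (style == "rule2") {
          doms <- sample.int(5, 3)
          z[2 * doms - sample(0:1, 3, replace = TRUE)] <-
            -1.05 - abs(rnorm(3, 0.3, 0.2))
        } else {
          lawton <- 4L
        }
      }
      status <- classify_jak_bondi(z, lawton)$status
      if (status == (if (is_mci) "MCI" else "CN"))
        return(c(as.list(z), list(lawton = lawton)))
    }
    stop("could not realize a score profile for the assigned status")
  }
  rows <- lapply(sim$covariates$mci == 1L, draw_one)
  scores <- do.call(rbind, lapply(rows, function(r) unlist(r)))
  colnames(scores) <- c(NEUROPSYCH_INSTRUMENTS, "lawton_brody")
  out <- tibble::as_tibble(scores)
  out$lawton_brody <- as.integer(out$lawton_brody)
  dplyr::bind_cols(tibble::tibble(subject_id = sim$covariates$subject_id), out)
}
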