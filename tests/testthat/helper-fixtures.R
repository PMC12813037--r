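# fixture builders shared across test files; all randomness is seeded by the
# caller

# constant 800 ms tachogram for one subject-day
make_constant_rr <- function(n_beats = 50, rr = 800, subject = "S1", day = 1L) {
  tibble::tibble(subject_id = subject, day_index = day,
                 beat_time_s = cumsum(rep(rr / 1000, n_beats)),
                 rr_ms = rep(rr, n_beats), interpolated = FALSE)
}

# profiles + covariates for a constant-effect cohort:
# y_i(t) = b0 + b1 * x_i + b_i + eps, all curves flat
make_flat_cohort <- function(n = 30, b0 = 2, b1 = 1, sigma_b = 0.5,
                             sigma_eps = 0.7, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  x <- rbinom(n, 1, 0.4)
  b <- rnorm(n, 0, sigma_b)
  covariates <- tibble::tibble(
    subject_id = ids, age = rnorm(n, 78, 5),
    sex = sample(c("male", "female"), n, replace = TRUE),
    ethnicity = sample(c("nh_white", "nh_black", "other"), n, replace = TRUE),
    education = rnorm(n, 15, 3), mci = x,
    depression = rbinom(n, 1, 0.2), diabetes = rbinom(n, 1, 0.2),
    hypertension = rbinom(n, 1, 0.5))
  obs <- expand.grid(i = seq_len(n), bin = 0:287)
  profiles <- tibble::tibble(
    subject_id = ids[obs$i], bin = obs$bin,
    y = b0 + b1 * x[obs$i] + b[obs$i] + rnorm(nrow(obs), 0, sigma_eps),
    n_days_contributing = 1L)
  list(profiles = profiles, covariates = covariates, x = x, b = b)
}

# one parameter-recovery replicate under the recovery conditions
# (sigma_b = 0.3, sigma_eps = 1.0, full wear); returns the fitted model
run_recovery_replicate <- function(seed, n_subjects = 81, n_days = 8,
                                   depth = 0.6) {
  cfg <- generator_config(n_subjects = n_subjects, sigma_b = 0.3,
                          sigma_eps = 1.0, n_days = n_days,
                          mci_effect_profile = raised_cosine_dip(depth, 0, 6),
                          seed = seed)
  sim <- simulate_cohort(cfg)
  epochs <- simulate_epochs_direct(sim, wear = FALSE)
  design <- build_design(build_profiles(epochs), sim$covariates)
  list(fit = fosr_fit(design), truth = sim$truth)
}

# minimal fit stub for interval/window geometry tests
make_fit_stub <- function(estimate, se) {
  structure(list(
    coefficients = matrix(estimate, ncol = 1,
                          dimnames = list(NULL, "mci")),
    se = matrix(se, ncol = 1, dimnames = list(NULL, "mci")),
    grid_hours = bin_to_hour(0:287)), class = "hrv_fosr_fit")
}
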