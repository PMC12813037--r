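test_that("cohort simulation matches configured margins and is deterministic", {
  cfg <- generator_config(n_subjects = 81, prop_mci = 0.247, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$covariates), 81)
  expect_equal(sum(sim$covariates$mci), 20)
  expect_true(all(sim$covariates$age >= 70))
  expect_setequal(unique(sim$covariates$ethnicity) %in%
                    c("nh_white", "nh_black", "other"), TRUE)

  none <- simulate_cohort(generator_config(n_subjects = 10, prop_mci = 0,
                                           seed = 3))
  expect_equal(sum(none$covariates$mci), 0)

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$covariates, sim2$covariates)
  expect_identical(sim$truth$beta_curves, sim2$truth$beta_curves)
  expect_identical(sim$truth$subject_intercepts,
                   sim2$truth$subject_intercepts)
})

test_that("invalid generator configuration errors name the offending field", {
  expect_error(generator_config(prop_mci = 1.5), "prop_mci")
  expect_error(generator_config(sigma_b = -1), "sigma_b")
  expect_error(generator_config(sigma_eps = -0.1), "sigma_eps")
  expect_error(generator_config(rsa_freq_hz = 0.5), "rsa_freq_hz")
  expect_error(generator_config(artifact_rate = 2), "artifact_rate")
  expect_error(generator_config(covariate_effects = list(bmi = 1)),
               "covariate_effects")
})

test_that("truth curves live on the 288-bin grid and wrap continuously", {
  sim <- simulate_cohort(generator_config(seed = 1))
  expect_equal(nrow(sim$truth$beta_curves), 288)
  # periodicity: step across the midnight wrap comparable to interior steps
  for (k in c("intercept", "mci")) {
    curve <- sim$truth$beta_curves[, k]
    wrap_step <- abs(curve[1] - curve[288])
    max_interior <- max(abs(diff(curve)))
    expect_lte(wrap_step, max_interior + 1e-12)
  }
})

test_that("epoch-level truth evaluates the model equation", {
  # all curves zero, no intercept spread, no noise -> exactly zero
  cfg0 <- generator_config(n_subjects = 5, prop_mci = 0.4,
                           mean_profile = constant_curve(0),
                           mci_effect_profile = constant_curve(0),
                           covariate_effects = list(),
                           sigma_b = 0, sigma_eps = 0, seed = 2)
  sim0 <- simulate_cohort(cfg0)
  expect_equal(epoch_lnhf_truth(sim0$truth, "S001", 0:287), rep(0, 288))

  # flat 4.5 intercept plus a -0.6 midnight dip for an MCI subject
  cfg1 <- generator_config(n_subjects = 4, prop_mci = 0.5,
                           mean_profile = constant_curve(4.5),
                           mci_effect_profile = raised_cosine_dip(0.6, 0, 6),
                           covariate_effects = list(),
                           sigma_b = 0, sigma_eps = 0, seed = 2)
  sim1 <- simulate_cohort(cfg1)
  mci_id <- sim1$covariates$subject_id[sim1$covariates$mci == 1][1]
  cn_id <- sim1$covariates$subject_id[sim1$covariates$mci == 0][1]
  expect_equal(epoch_lnhf_truth(sim1$truth, mci_id, 0L), 3.9)
  expect_equal(epoch_lnhf_truth(sim1$truth, cn_id, 0L), 4.5)

  expect_error(epoch_lnhf_truth(sim1$truth, "nobody", 0L), "unknown subject")
})

test_that("epoch noise SD matches sigma_eps (Monte Carlo)", {
  cfg <- generator_config(n_subjects = 2, sigma_eps = 1, seed = 9)
  sim <- simulate_cohort(cfg)
  set.seed(42)
  draws <- epoch_lnhf_truth(sim$truth, "S001", rep(100L, 1e4), noisy = TRUE)
  expect_lt(abs(sd(draws) - 1), 0.05)
})

test_that("RR synthesis hits the sinusoid amplitude identity", {
  cfg <- generator_config()
  # target 450 ms^2 -> A = sqrt(2 * 450) = 30 ms; the beats sample the
  # sinusoid, so recover A from its variance (A^2/2) rather than the extremes
  seg <- simulate_rr_epoch(log(450), cfg)
  n <- nrow(seg)
  A_hat <- sqrt(2 * var(seg$rr_ms) * (n - 1) / n)
  expect_equal(A_hat, 30, tolerance = 0.01)
  expect_lte(max(seg$rr_ms), cfg$rr_base_ms + 30 + 1e-9)
  expect_gte(min(seg$rr_ms), cfg$rr_base_ms - 30 - 1e-9)

  # vanishing target power -> constant series
  flat <- simulate_rr_epoch(-20, cfg)
  expect_lt(sd(flat$rr_ms), 1e-3)

  # non-physiological amplitude rejected
  expect_error(simulate_rr_epoch(log(800^2), cfg), "non-physiological")
})

test_that("RR round trip recovers the target Ln(HF) through the spectral path", {
  cfg <- generator_config()
  for (target in c(log(100), log(450), 4.5, 6.5)) {
    seg <- simulate_rr_epoch(target, cfg)
    recovered <- log(band_power(interval_spectrum(seg$rr_ms)))
    expect_lt(abs(recovered - target), 0.05)
  }
})

test_that("band-power identity A^2/2 holds across amplitudes", {
  cfg <- generator_config()
  for (A in c(5, 15, 30, 50)) {
    seg <- simulate_rr_epoch(log(A^2 / 2), cfg)
    hf <- band_power(interval_spectrum(seg$rr_ms))
    expect_lt(abs(hf - A^2 / 2) / (A^2 / 2), 0.02)
  }
})

test_that("wear and artifact model behaves at its extremes and is reproducible", {
  cfg_clean <- generator_config(
    n_subjects = 1, n_days = 2, artifact_rate = 0,
    wear_model = list(day_dropout = 0, retention = 1), seed = 5)
  sim <- simulate_cohort(cfg_clean)
  rec <- simulate_subject_recording(sim, "S001")
  epochs <- preprocess_rr(rec)
  expect_equal(unname(table(epochs$day_index[epochs$valid])),
               c(288L, 288L), ignore_attr = TRUE)
  expect_equal(sum(epochs$frac_interpolated), 0)

  rec2 <- simulate_subject_recording(sim, "S001")
  expect_identical(rec, rec2)
})

test_that("artifact corruption is detected beat-for-beat downstream", {
  # 0.5 corruption rate on a ~100-beat stretch: flagged count within 3 SD of
  # the binomial expectation
  set.seed(31)
  n <- 100
  rr <- make_constant_rr(n_beats = n)
  hit <- runif(n) < 0.5
  rr$rr_ms[hit] <- rr$rr_ms[hit] * sample(c(0.55, 1.6), sum(hit), TRUE)
  cleaned <- flag_and_interpolate(rr)
  n_detected <- sum(cleaned$interpolated) + attr(cleaned, "n_dropped")
  expect_lt(abs(n_detected - sum(hit)), 3 * sqrt(n * 0.25) + 1)
})
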