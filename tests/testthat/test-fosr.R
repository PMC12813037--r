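test_that("cyclic B-spline basis is periodic and spans the cSplineDes space", {
  h <- seq(0, 23.95, by = 0.05)
  B <- cyclic_bspline_basis(h, 24)
  expect_equal(rowSums(B), rep(1, length(h)))  # partition of unity
  # periodic: approaching 24 h returns to the value at 0
  expect_equal(cyclic_bspline_basis(1e-9, 24), cyclic_bspline_basis(24 - 1e-9, 24),
               tolerance = 1e-6)
  skip_if_not_installed("mgcv")
  B2 <- mgcv::cSplineDes(h, seq(0, 24, length.out = 25))
  hit <- FALSE
  for (r in 0:23) {
    idx <- ((0:23 + r) %% 24) + 1
    if (max(abs(B[, idx] - B2)) < 1e-8) { hit <- TRUE; break }
  }
  expect_true(hit)  # identical basis up to circular column rotation
})

test_that("cyclic difference penalty annihilates constants only", {
  P <- diff_penalty(24, order = 2, cyclic = TRUE)
  expect_equal(drop(P %*% rep(1, 24)), rep(0, 24))
  e <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(e < max(e) * 1e-9), 1)  # rank n - 1
})

test_that("design centering, covariate sets, and join errors behave as specified", {
  fix <- make_flat_cohort(n = 12, seed = 2)
  fix$covariates$age <- rep(c(70, 80, 90), 4)
  d <- build_design(fix$profiles, fix$covariates)
  expect_equal(unique(d$x[, "age_c"]), c(-10, 0, 10))
  expect_lt(abs(mean(d$x[, "age_c"])), 1e-10)
  expect_lt(abs(mean(d$x[, "education_c"])), 1e-10)
  expect_equal(ncol(d$x), 7)

  d2 <- build_design(fix$profiles, fix$covariates, model = "secondary")
  expect_equal(ncol(d2$x), 10)

  expect_error(build_design(fix$profiles, fix$covariates[-1, ], "primary"),
               "S001")

  collinear <- fix$covariates
  collinear$age <- 78  # age_c identically zero
  expect_error(build_design(fix$profiles, collinear), "age_c")
})

test_that("with flat-forced curves the fit reduces to a direct GLS oracle", {
  fix <- make_flat_cohort(n = 12, seed = 5)
  design <- build_design(fix$profiles, fix$covariates)
  lambda_b <- 2.0
  lam <- c(rep(1e9, 7), 2.0)
  names(lam) <- c(colnames(design$x), "subject")
  fit <- fosr_fit(design, basis_spec(n_basis = 4), lambda = lam)

  # curves are constant
  expect_lt(max(apply(fit$coefficients, 2, function(c) diff(range(c)))), 1e-6)

  # independent GLS oracle at the same variance ratio (Woodbury form)
  obs <- design$obs
  subj <- match(obs$subject_id, design$ids)
  X <- design$x[subj, ]
  Zb <- matrix(0, nrow(obs), 12)
  Zb[cbind(seq_len(nrow(obs)), subj)] <- 1
  Vinv_y <- function(v) v - Zb %*% solve(diag(12) * lambda_b + crossprod(Zb),
                                         crossprod(Zb, v))
  beta_gls <- solve(t(X) %*% Vinv_y(X), t(X) %*% Vinv_y(obs$y))
  expect_equal(unname(fit$coefficients[1, ]), unname(drop(beta_gls)),
               tolerance = 1e-4)
})

test_that("REML fit matches lme4 on constant-effect data", {
  skip_if_not_installed("lme4")
  fix <- make_flat_cohort(n = 30, seed = 42)
  design <- build_design(fix$profiles, fix$covariates)
  fit <- fosr_fit(design)

  obs <- design$obs
  subj <- match(obs$subject_id, design$ids)
  df <- data.frame(y = obs$y, design$x[subj, -1], id = obs$subject_id)
  form <- stats::as.formula(paste("y ~", paste(colnames(design$x)[-1],
                                               collapse = "+"), "+ (1 | id)"))
  lmm <- lme4::lmer(form, df, REML = TRUE)
  expect_equal(mean(fit$coefficients[, "mci"]),
               unname(lme4::fixef(lmm)["mci"]), tolerance = 1e-3)
  # the penalized model coincides with lmer only in the flat limit; finite
  # REML-chosen smoothing leaves a small model difference in the sigmas
  expect_equal(fit$sigma_b, sqrt(unlist(lme4::VarCorr(lmm))[[1]]),
               tolerance = 5e-3, ignore_attr = TRUE)
  expect_equal(fit$sigma_eps, stats::sigma(lmm), tolerance = 5e-3)
  # the scalar x effect is recovered near its simulated value of 1
  expect_lt(abs(mean(fit$coefficients[, "mci"]) - 1), 0.5)
})

test_that("the fit is deterministic and curves wrap continuously", {
  rep1 <- run_recovery_replicate(301, n_subjects = 25, n_days = 2)
  rep2 <- run_recovery_replicate(301, n_subjects = 25, n_days = 2)
  expect_identical(rep1$fit$coefficients, rep2$fit$coefficients)
  expect_identical(rep1$fit$lambda, rep2$fit$lambda)

  curve <- rep1$fit$coefficients[, "mci"]
  wrap_step <- abs(curve[1] - curve[288])
  expect_lte(wrap_step, max(abs(diff(curve))) * 2 + 1e-9)
})

test_that("pointwise intervals follow normal-quantile arithmetic", {
  est <- rep(-0.6, 288); se <- rep(0.2, 288)
  stub <- make_fit_stub(est, se)
  ci <- pointwise_ci(stub, 0.95)
  expect_equal(ci$lower[1], -0.992, tolerance = 1e-3)
  expect_equal(ci$upper[1], -0.208, tolerance = 1e-3)

  # SE -> 0 collapses the band onto the estimate
  ci0 <- pointwise_ci(make_fit_stub(est, rep(0, 288)), 0.95)
  expect_equal(ci0$lower, ci0$estimate)
  expect_equal(ci0$upper, ci0$estimate)

  expect_error(pointwise_ci(stub, 1.2), "level")
  expect_error(pointwise_ci(stub, 0), "level")
})

test_that("significance windows merge across midnight and report clock times", {
  # significant (below zero) on bins 0-83 and 228-287: one wrapped window
  est <- rep(0, 288); se <- rep(0.1, 288)
  est[c(1:84, 229:288)] <- -1
  w <- significance_windows(make_fit_stub(est, se), "mci")
  expect_equal(nrow(w), 1)
  expect_equal(w$start_clock, "19:00")
  expect_equal(w$end_clock, "07:00")
  expect_equal(w$sign, "below")
  expect_equal(w$n_bins, 144L)

  # no exclusion anywhere
  w0 <- significance_windows(make_fit_stub(rep(0, 288), se), "mci")
  expect_equal(nrow(w0), 0)

  # single-bin excursion above zero -> one 5-min window
  est1 <- rep(0, 288); est1[101] <- 2
  w1 <- significance_windows(make_fit_stub(est1, se), "mci")
  expect_equal(nrow(w1), 1)
  expect_equal(w1$n_bins, 1L)
  expect_equal(w1$sign, "above")
  expect_equal(w1$start_clock, "08:20")
  expect_equal(w1$end_clock, "08:25")
})

test_that("Cohen's d is the difference over the reference SD", {
  expect_equal(cohens_d(0.6, 0.8), 0.75)
  expect_identical(cohens_d(0, 3), 0)
  expect_equal(cohens_d(1.2, 0.8), 1.5)
  expect_error(cohens_d(0.6, 0), "positive")
  expect_error(cohens_d(0.6, -1), "positive")
})

test_that("under a null MCI effect the coefficient curve stays within its bands", {
  excl <- replicate(4, NULL)
  frac_excluded <- vapply(1:4, function(s) {
    rep <- run_recovery_replicate(7000 + s, n_subjects = 81, n_days = 8,
                                  depth = 0)
    ci <- pointwise_ci(rep$fit, 0.95, "mci")
    expect_lt(max(abs(rep$fit$coefficients[, "mci"])),
              3 * max(rep$fit$se[, "mci"]) + 1e-9)
    mean(ci$lower > 0 | ci$upper < 0)
  }, 0)
  expect_lte(mean(frac_excluded), 0.08)  # near-nominal pointwise type I error
})

test_that("pointwise bands cover the true effect curve at ~95%", {
  covered <- vapply(1:12, function(s) {
    rep <- run_recovery_replicate(5000 + s, n_subjects = 40, n_days = 4)
    truth <- rep$truth$beta_curves[, "mci"]
    ci <- pointwise_ci(rep$fit, 0.95, "mci")
    mean(ci$lower <= truth & truth <= ci$upper)
  }, 0)
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.995)
})

test_that("fit serialization and tidy export carry the curve tables", {
  rep <- run_recovery_replicate(88, n_subjects = 20, n_days = 2)
  tidy <- fit_tidy(rep$fit)
  expect_equal(nrow(tidy), 288 * 7)
  expect_setequal(unique(tidy$coefficient), colnames(rep$fit$coefficients))
  path <- tempfile(fileext = ".json")
  write_fit_json(rep$fit, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$n_subjects, 20)
  expect_equal(length(parsed$curves$mci$estimate), 288)
})
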