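test_that("constant tachograms carry no spectral power", {
  sp <- interval_spectrum(rep(800, 100))
  expect_lt(max(sp$power_ms2), 1e-18)
  expect_equal(band_power(sp), 0, tolerance = 1e-18)
})

test_that("a modulation line appears at its analytic frequency", {
  tau <- cumsum(rep(0.8, 375))
  rr <- 800 + 30 * sin(2 * pi * 0.25 * tau)
  sp <- interval_spectrum(rr)
  expect_equal(sp$freq_hz[which.max(sp$power_ms2)], 0.25,
               tolerance = 1 / (375 * 0.8))
})

test_that("peak location is within one frequency bin across heart rates", {
  for (rbar in c(600, 800, 1000, 1200)) {
    n <- round(300 * 1000 / rbar)
    tau <- cumsum(rep(rbar / 1000, n))
    rr <- rbar + 20 * sin(2 * pi * 0.25 * tau)
    sp <- interval_spectrum(rr)
    bin_width <- 1 / (n * rbar / 1000)
    peak <- sp$freq_hz[which.max(sp$power_ms2)]
    expect_lt(abs(peak - 0.25), bin_width)
  }
})

test_that("total power obeys Parseval for white-noise intervals", {
  set.seed(8)
  for (rep in 1:3) {
    rr <- 800 + rnorm(375, 0, 10)
    sp <- interval_spectrum(rr, spectral_config(detrend = "mean"))
    v <- mean((rr - mean(rr))^2)
    expect_lt(abs(sum(sp$power_ms2) - v) / v, 1e-10)  # exact identity
    expect_lt(abs(sum(sp$power_ms2) - 100) / 100, 0.05 * 3)  # vs nominal SD
  }
})

test_that("band power isolates the 0.15-0.40 Hz band", {
  tau <- cumsum(rep(0.8, 375))
  in_band <- 800 + 30 * sin(2 * pi * 0.25 * tau)
  expect_equal(band_power(interval_spectrum(in_band)), 450,
               tolerance = 450 * 0.02)
  below <- 800 + 30 * sin(2 * pi * 0.10 * tau)
  expect_lt(band_power(interval_spectrum(below)), 450 * 0.02)
})

test_that("scale equivariance: deviations x c give power x c^2", {
  set.seed(12)
  dev <- rnorm(375, 0, 8)
  base <- band_power(interval_spectrum(800 + dev))
  for (c in c(0.5, 2, 3)) {
    scaled <- band_power(interval_spectrum(800 + c * dev))
    expect_equal(scaled / base, c^2, tolerance = 1e-8)
  }
})

test_that("interval spectrum agrees with a brute-force DFT oracle", {
  set.seed(21)
  rr <- 800 + rnorm(128, 0, 12)
  sp <- interval_spectrum(rr, spectral_config(detrend = "mean"))
  x <- rr - mean(rr)
  n <- length(x)
  oracle <- vapply(seq_len(n %/% 2), function(j) {
    re <- sum(x * cos(-2 * pi * j * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * j * (0:(n - 1)) / n))
    p <- 2 * (re^2 + im^2) / n^2
    if (n %% 2 == 0 && j == n %/% 2) p / 2 else p
  }, 0)
  expect_lt(max(abs(sp$power_ms2 - oracle)) / max(oracle), 1e-6)
})

test_that("too-few-beat epochs are rejected with a reason", {
  expect_error(interval_spectrum(rep(800, 10)), "too few beats")
  shells <- tibble::tibble(subject_id = "S1", day_index = 1L, bin = 0:1,
                           n_beats = c(10L, 40L), frac_interpolated = 0,
                           rr = list(rep(800, 10), rep(800, 40)))
  out <- compute_epoch_hf(shells)
  expect_equal(out$invalid_reason[1], "too few beats")
  expect_false(out$valid[1])
})

test_that("log transform floors tiny power instead of returning -Inf", {
  expect_equal(ln_transform(450), log(450))
  expect_equal(ln_transform(450), 6.109, tolerance = 1e-3)
  expect_equal(ln_transform(1), 0)
  expect_true(is.na(ln_transform(0)))
  expect_true(is.na(ln_transform(1e-7)))
  expect_error(ln_transform(-1), "negative")
})

test_that("the batched epoch pass matches the per-epoch path", {
  set.seed(33)
  rr_list <- lapply(1:20, function(i) {
    n <- sample(340:380, 1)
    tau <- cumsum(rep(0.8, n))
    800 + runif(1, 5, 40) * sin(2 * pi * runif(1, 0.18, 0.35) * tau) +
      rnorm(n, 0, 5)
  })
  shells <- tibble::tibble(subject_id = "S1", day_index = 1L,
                           bin = 0:19, n_beats = lengths(rr_list),
                           frac_interpolated = 0, rr = rr_list)
  batch <- compute_epoch_hf(shells)
  single <- vapply(rr_list, function(r) band_power(interval_spectrum(r)), 0)
  expect_equal(batch$hf_ms2, single, tolerance = 1e-10)
  expect_equal(batch$ln_hf, log(single), tolerance = 1e-10)
})

test_that("epochs exceeding the interpolation threshold are invalidated", {
  shells <- tibble::tibble(subject_id = "S1", day_index = 1L, bin = 0:2,
                           n_beats = 100L,
                           frac_interpolated = c(0, 0.2, 0.21),
                           rr = replicate(3, 800 + rnorm(100, 0, 10),
                                          simplify = FALSE))
  out <- compute_epoch_hf(shells)
  expect_equal(out$valid, c(TRUE, TRUE, FALSE))
  expect_equal(out$invalid_reason[3], "interpolation fraction")
})
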