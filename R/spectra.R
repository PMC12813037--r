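#' Spectral analysis configuration
#'
#' @param hf_low_hz,hf_high_hz High-frequency band edges (Hz); the band is
#'   half-open `[hf_low_hz, hf_high_hz)`.
#' @param detrend Per-epoch detrending of the interval sequence: `"linear"`
#'   (default; suppresses low-frequency leakage into the HF band) or
#'   `"mean"`.
#' @param window Taper: `"none"` (default; keeps the sinusoid band-power
#'   identity A^2/2 exact) or `"hann"` (power-normalized).
#' @param power_floor Epochs with HF power at or below this floor (ms^2) are
#'   marked invalid instead of yielding `-Inf` on the log scale.
#' @param min_beats Minimum beats per epoch for a spectrum.
#' @return A validated `hrv_spectral_config` list.
#' @export
spectral_config <- function(hf_low_hz = 0.15, hf_high_hz = 0.40,
                            detrend = c("linear", "mean"),
                            window = c("none", "hann"),
                            power_floor = 1e-6, min_beats = 32L) {
  detrend <- match.arg(detrend)
  window <- match.arg(window)
  if (!(hf_low_hz > 0 && hf_low_hz < hf_high_hz))
    stop_config("hf_low_hz", "need 0 < hf_low_hz < hf_high_hz")
  structure(list(hf_low_hz = hf_low_hz, hf_high_hz = hf_high_hz,
                 detrend = detrend, window = window,
                 power_floor = power_floor, min_beats = as.integer(min_beats)),
            class = "hrv_spectral_config")
}

detrend_vec <- function(x, method) {
  n <- length(x)
  if (method == "mean") return(x - mean(x))
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

#' Interval spectrum of one epoch's RR sequence
#'
#' Discrete Fourier transform of the detrended beat-indexed interval
#' sequence. Frequencies are cycles per beat rescaled to Hz through the mean
#' interval: `f_j = j / (N * rbar)` with `rbar` the mean RR in seconds. The
#' one-sided power is normalized so that total power equals the variance of
#' the (detrended) interval sequence (Parseval).
#'
#' @param rr_ms Interval sequence of one epoch (ms), at least `min_beats`
#'   beats.
#' @param config A [spectral_config()].
#' @return List with `freq_hz`, `power_ms2` (summed power per frequency bin,
#'   not density), and `mean_rr_s`.
#' @export
#' @examples
#' tau <- cumsum(rep(0.8, 375))
#' rr <- 800 + 30 * sin(2 * pi * 0.25 * tau)
#' sp <- interval_spectrum(rr)
#' sp$freq_hz[which.max(sp$power_ms2)]  # ~0.25 Hz
interval_spectrum <- function(rr_ms, config = spectral_config()) {
  n <- length(rr_ms)
  if (n < config$min_beats)
    stop("too few beats for a spectrum (", n, " < ", config$min_beats, ")",
         call. = FALSE)
  x <- detrend_vec(rr_ms, config$detrend)
  wnorm <- 1
  if (config$window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    wnorm <- mean(w^2)
    x <- x * w
  }
  X <- fft(x)
  half <- n %/% 2
  j <- seq_len(half)
  power <- 2 * Mod(X[j + 1])^2 / n^2 / wnorm
  if (n %% 2 == 0) power[half] <- power[half] / 2  # Nyquist bin not doubled
  rbar <- mean(rr_ms) / 1000
  list(freq_hz = j / (n * rbar), power_ms2 = power, mean_rr_s = rbar)
}

#' HF band power of a spectrum
#'
#' Sums power over frequency bins with `hf_low_hz <= f < hf_high_hz`.
#'
#' @param spectrum Output of [interval_spectrum()].
#' @param config A [spectral_config()].
#' @return HF power in ms^2 (non-negative).
#' @export
band_power <- function(spectrum, config = spectral_config()) {
  sel <- spectrum$freq_hz >= config$hf_low_hz &
    spectrum$freq_hz < config$hf_high_hz
  if (!any(sel))
    stop("HF band contains no frequency bins at this epoch length",
         call. = FALSE)
  sum(spectrum$power_ms2[sel])
}

#' Natural-log transform of HF power
#'
#' @param hf_ms2 HF power values (ms^2); must be non-negative.
#' @param power_floor Values at or below this floor become `NA` (the epoch is
#'   invalid) instead of `-Inf`.
#' @return Ln(HF) values (ln ms^2), `NA` where floored.
#' @export
ln_transform <- function(hf_ms2, power_floor = 1e-6) {
  if (any(hf_ms2 < 0, na.rm = TRUE))
    stop("negative HF power: band_power contract violated", call. = FALSE)
  out <- rep(NA_real_, length(hf_ms2))
  ok <- !is.na(hf_ms2) & hf_ms2 > power_floor
  out[ok] <- log(hf_ms2[ok])
  out
}

#' Fill HF power and Ln(HF) for a table of epoch shells
#'
#' Batch spectral pass over the epoch shells produced by [segment_epochs()].
#' Epochs are grouped by beat count so the DFT runs on matrices. The validity
#' flag combines the interpolation-fraction rule with spectral viability
#' (enough beats, non-empty band, power above the floor);
#' `invalid_reason` records why an epoch failed.
#'
#' @param shells Epoch shell tibble with list-column `rr` (from
#'   [segment_epochs()]).
#' @param config A [spectral_config()].
#' @param max_interp_frac Passed to [epoch_validity()].
#' @return Epoch tibble with `hf_ms2`, `ln_hf`, `valid`, `invalid_reason`
#'   columns (the `rr` list-column is dropped).
#' @export
compute_epoch_hf <- function(shells, config = spectral_config(),
                             max_interp_frac = 0.2) {
  n_epochs <- nrow(shells)
  hf <- rep(NA_real_, n_epochs)
  reason <- rep(NA_character_, n_epochs)
  ns <- lengths(shells$rr)
  too_few <- ns < config$min_beats
  reason[too_few] <- "too few beats"

  for (n in unique(ns[!too_few])) {
    idx <- which(ns == n & !too_few)
    M <- matrix(unlist(shells$rr[idx], use.names = FALSE), nrow = n)
    rbar <- colMeans(M) / 1000
    # detrend columns
    M <- M - matrix(colMeans(M), nrow = n, ncol = length(idx), byrow = TRUE)
    if (config$detrend == "linear") {
      t <- seq_len(n) - (n + 1) / 2
      slope <- drop(t %*% M) / sum(t * t)
      M <- M - outer(t, slope)
    }
    if (config$window == "hann") {
      w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
      M <- M * w / sqrt(mean(w^2))
    }
    X <- stats::mvfft(M)
    half <- n %/% 2
    P <- 2 * Mod(X[1 + seq_len(half), , drop = FALSE])^2 / n^2
    if (n %% 2 == 0) P[half, ] <- P[half, ] / 2
    # per-column band limits: f_j = j/(n * rbar) in [lo, hi)
    jlo <- pmax(ceiling(config$hf_low_hz * n * rbar), 1)
    jhi <- pmin(ceiling(config$hf_high_hz * n * rbar) - 1, half)
    cumP <- apply(P, 2, cumsum)
    empty <- jlo > jhi
    bp <- rep(NA_real_, length(idx))
    ok <- which(!empty)
    if (length(ok) > 0) {
      top <- cumP[cbind(jhi[ok], ok)]
      bot <- ifelse(jlo[ok] > 1, cumP[cbind(pmax(jlo[ok] - 1, 1), ok)], 0)
      bp[ok] <- top - bot
    }
    hf[idx] <- bp
    reason[idx[empty]] <- "empty HF band"
  }

  ln_hf <- ln_transform(hf, config$power_floor)
  reason[is.na(reason) & !is.na(hf) & is.na(ln_hf)] <- "power at floor"
  interp_ok <- epoch_validity(shells$frac_interpolated, max_interp_frac)
  reason[is.na(reason) & !interp_ok] <- "interpolation fraction"
  out <- dplyr::select(shells, -"rr")
  out$hf_ms2 <- hf
  out$ln_hf <- ln_hf
  out$valid <- interp_ok & !is.na(ln_hf)
  out$invalid_reason <- reason
  out
}
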