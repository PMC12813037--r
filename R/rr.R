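#' Flag and interpolate RR-interval artifacts
#'
#' Artifact detection on the beat-indexed interval sequence: each interval is
#' compared with the running median of the last `window` accepted (clean)
#' intervals; a relative deviation above `deviation_threshold` flags the
#' beat. Flagged runs of up to `max_run` consecutive beats are replaced by
#' the local median (interpolated); longer runs are excluded entirely, since
#' interpolation is no longer credible. Beat times are rebuilt cumulatively
#' within contiguous segments of the recording (a gap larger than `gap_s`
#' seconds starts a new segment anchored at its original start time, so
#' clock alignment across wear gaps is preserved).
#'
#' @param series RR series tibble (`subject_id`, `day_index`, `beat_time_s`,
#'   `rr_ms`, `interpolated`), time-ordered within day.
#' @param deviation_threshold Relative deviation from the local median that
#'   flags a beat (default 0.2 = 20%).
#' @param window Number of accepted neighbor intervals in the running median.
#' @param max_run Longest run of flagged beats that is interpolated rather
#'   than dropped.
#' @param gap_s Time gap that separates contiguous segments.
#' @return The cleaned series, with `interpolated` set on corrected beats and
#'   dropped beats removed. Attribute `n_dropped` counts exclusions. Series
#'   shorter than `window + 1` beats are returned unchanged with a warning.
#' @export
#' @examples
#' rr <- tibble::tibble(subject_id = "S1", day_index = 1,
#'                      beat_time_s = cumsum(rep(0.8, 50)),
#'                      rr_ms = rep(800, 50), interpolated = FALSE)
#' rr$rr_ms[25] <- 1200
#' cleaned <- flag_and_interpolate(rr)
#' cleaned$rr_ms[25]  # back to 800, flagged interpolated
flag_and_interpolate <- function(series, deviation_threshold = 0.2,
                                 window = 5L, max_run = 3L, gap_s = 2) {
  stopifnot(all(c("subject_id", "day_index", "beat_time_s", "rr_ms") %in%
                  names(series)))
  if (nrow(series) < window + 1) {
    warning("series has fewer than window + 1 beats; returned unchanged")
    attr(series, "n_dropped") <- 0L
    return(series)
  }
  n_dropped <- 0L
  out <- series |>
    dplyr::group_by(.data$subject_id, .data$day_index) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < window + 1) return(df)
      stopifnot(!is.unsorted(df$beat_time_s))
      res <- clean_rr_cpp(df$rr_ms, deviation_threshold, as.integer(window),
                          as.integer(max_run))
      df$rr_ms <- res$rr_ms
      df$interpolated <- df$interpolated | res$interpolated
      keep <- !res$dropped
      n_dropped <<- n_dropped + sum(!keep)
      df <- df[keep, ]
      # rebuild times cumulatively within contiguous segments
      if (nrow(df) > 0) {
        seg <- cumsum(c(TRUE, diff(df$beat_time_s) > gap_s))
        cs <- cumsum(df$rr_ms) / 1000
        first <- !duplicated(seg)
        offset <- (df$beat_time_s - cs)[first]
        df$beat_time_s <- offset[seg] + cs
      }
      df
    }) |>
    dplyr::ungroup()
  out <- dplyr::select(out, dplyr::all_of(names(series)))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Segment a cleaned RR series into clock-aligned 5-minute epochs
#'
#' Bins are half-open clock intervals anchored at local midnight: bin k holds
#' beats with `beat_time_s` in `[300k, 300(k+1))`. One shell is produced per
#' (day, bin) containing at least 2 beats; empty bins are simply absent.
#'
#' @param series Cleaned RR series tibble.
#' @return Epoch shell tibble (`subject_id`, `day_index`, `bin`, `n_beats`,
#'   `frac_interpolated`) plus a list-column `rr` with each epoch's interval
#'   sequence (ms), consumed by the spectral stage.
#' @export
segment_epochs <- function(series) {
  series <- dplyr::filter(series, .data$beat_time_s >= 0,
                          .data$beat_time_s < 86400)
  if (nrow(series) == 0)
    return(tibble::tibble(subject_id = character(), day_index = integer(),
                          bin = integer(), n_beats = integer(),
                          frac_interpolated = numeric(), rr = list()))
  series$bin <- as.integer(series$beat_time_s %/% BIN_SECONDS)
  out <- series |>
    dplyr::group_by(.data$subject_id, .data$day_index, .data$bin) |>
    dplyr::summarise(n_beats = dplyr::n(),
                     frac_interpolated = mean(.data$interpolated),
                     rr = list(.data$rr_ms), .groups = "drop") |>
    dplyr::filter(.data$n_beats >= 2L)
  out
}

#' Epoch validity under the interpolation-fraction rule
#'
#' An epoch is excluded when more than `max_interp_frac` of its RR intervals
#' required interpolation; the boundary (exactly 20%) is retained, since
#' exclusion applies to "more than" the threshold.
#'
#' @param frac_interpolated Fraction of interpolated beats per epoch.
#' @param max_interp_frac Exclusion threshold (default 0.2).
#' @return Logical vector: `TRUE` for valid epochs.
#' @export
epoch_validity <- function(frac_interpolated, max_interp_frac = 0.2) {
  stopifnot(all(frac_interpolated >= 0), all(frac_interpolated <= 1))
  frac_interpolated <= max_interp_frac
}
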