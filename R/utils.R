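`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clock time of a 5-minute bin
#'
#' Bins index the 288 five-minute epochs tiling a 24-h day, anchored at local
#' midnight: bin k covers `[300k, 300(k+1))` seconds.
#'
#' @param bin Integer bin index in `0:287`.
#' @return Hours since midnight (numeric, bin start).
#' @export
bin_to_hour <- function(bin) {
  stopifnot(all(bin >= 0L), all(bin <= 287L))
  bin * 5 / 60
}

#' @rdname bin_to_hour
#' @param hour Hours since midnight in `[0, 24)`.
#' @export
hour_to_bin <- function(hour) {
  as.integer(floor((hour %% 24) * 12))
}

format_clock <- function(hour) {
  h <- floor(hour)
  m <- round((hour - h) * 60)
  h <- h + m %/% 60
  m <- m %% 60
  sprintf("%02d:%02d", h, m)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# deterministic sub-seed derivation; keeps results below .Machine$integer.max
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483629) + 1L
}
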