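#' Smooth 24-hour curve specifications
#'
#' Coefficient curves for the data-generating model are specified as small
#' lists and evaluated on the 288-bin grid. Three shapes cover the study
#' design: a cosinor (mesor + single circadian harmonic) for the functional
#' intercept, a raised-cosine nocturnal dip for the MCI effect, and constants
#' for scalar covariate effects. All shapes are periodic on `[0, 24)` h.
#'
#' @param mesor Midline level (ln ms^2).
#' @param amplitude Circadian amplitude (ln ms^2).
#' @param acrophase Clock time of the peak, hours.
#' @return A curve spec object (list with class `hrv_curve`).
#' @seealso [eval_curve()]
#' @export
#' @examples
#' eval_curve(cosinor_curve(4.5, 0.7, 3), hours = c(0, 3, 15))
cosinor_curve <- function(mesor, amplitude = 0, acrophase = 3) {
  structure(list(type = "cosinor", mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase), class = "hrv_curve")
}

#' @rdname cosinor_curve
#' @param depth Dip depth at its center (positive number; the curve value at
#'   the center is `-depth`).
#' @param center Clock time of the dip center, hours (default midnight).
#' @param halfwidth Half-width of the dip window, hours; the curve is 0
#'   outside `center +/- halfwidth` (wrapping at midnight).
#' @export
raised_cosine_dip <- function(depth, center = 0, halfwidth = 6) {
  stopifnot(depth >= 0, halfwidth > 0, halfwidth <= 12)
  structure(list(type = "dip", depth = depth, center = center,
                 halfwidth = halfwidth), class = "hrv_curve")
}

#' @rdname cosinor_curve
#' @param value Constant effect per unit of the covariate.
#' @export
constant_curve <- function(value) {
  structure(list(type = "constant", value = value), class = "hrv_curve")
}

#' Evaluate a curve spec on clock times or the 288-bin grid
#'
#' @param curve A `hrv_curve` spec, a single number (treated as a constant
#'   curve), or a numeric vector of length 288 (used as-is).
#' @param hours Clock times in hours; defaults to the 288 bin-start times.
#' @return Numeric vector of curve values, one per time.
#' @export
eval_curve <- function(curve, hours = bin_to_hour(0:287)) {
  if (is.numeric(curve) && length(curve) == 1L) {
    return(rep(curve, length(hours)))
  }
  if (is.numeric(curve)) {
    stopifnot(length(curve) == N_BINS)
    return(curve[hour_to_bin(hours) + 1L])
  }
  stopifnot(inherits(curve, "hrv_curve"))
  switch(curve$type,
    cosinor = curve$mesor +
      curve$amplitude * cos(2 * pi * (hours - curve$acrophase) / 24),
    dip = {
      # signed circular distance from the dip center, in hours
      u <- (hours - curve$center + 12) %% 24 - 12
      val <- -curve$depth * cos(pi * u / (2 * curve$halfwidth))^2
      val[abs(u) > curve$halfwidth] <- 0
      val
    },
    constant = rep(curve$value, length(hours)),
    stop("unknown curve type: ", curve$type)
  )
}
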