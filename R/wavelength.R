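#' Piecewise-quadratic pixel-to-wavelength model
#'
#' Push-broom spectrographs map detector pixel index to band-center
#' wavelength through a fitted polynomial. The model is a list of segments,
#' each a half-open pixel interval `(lo, hi]` with quadratic coefficients
#' `(a2, a1, a0)` so that the wavelength at pixel `i` is
#' `a2*i^2 + a1*i + a0` nanometres.
#'
#' @param segments list of segments; each has `lo`, `hi` (pixel bounds,
#'   half-open `(lo, hi]`) and `coef` = c(a2, a1, a0).
#' @return An object of class `wavelength_model`.
#' @export
wavelength_model <- function(segments) {
  stopifnot(length(segments) >= 1L)
  lo <- vapply(segments, function(s) s$lo, 0)
  hi <- vapply(segments, function(s) s$hi, 0)
  o <- order(lo)
  segments <- segments[o]
  lo <- lo[o]; hi <- hi[o]
  if (any(hi <= lo)) {
    stop_beefhsi("segment bounds must satisfy lo < hi",
                 class = "beefhsi_wavelength_error")
  }
  if (length(segments) > 1L && any(lo[-1] != hi[-length(hi)])) {
    stop_beefhsi("segments must be contiguous and disjoint",
                 class = "beefhsi_wavelength_error")
  }
  structure(list(segments = segments), class = "wavelength_model")
}

#' The instrument's fitted wavelength model
#'
#' Coefficients of the fitted pixel-position/wavelength calibration of the
#' visible/near-infrared push-broom system this package models: two
#' quadratic branches covering detector pixels (50, 1000] and (1000, 1940],
#' spanning roughly 795 down to 388 nm (wavelength decreases with pixel
#' index).
#'
#' @return A [wavelength_model].
#' @export
default_wavelength_model <- function() {
  wavelength_model(list(
    list(lo = 50,   hi = 1000, coef = c(-7.37e-06, -0.201, 803.26)),
    list(lo = 1000, hi = 1940, coef = c(-2.09e-06, -0.213, 809.19))
  ))
}

#' Evaluate a wavelength model at detector pixel indices
#'
#' @param model a [wavelength_model].
#' @param i numeric vector of pixel indices; each must fall in one of the
#'   model's half-open segment intervals.
#' @return wavelengths in nm, same length as `i`.
#' @export
evaluate_wavelength_model <- function(model, i) {
  stopifnot(inherits(model, "wavelength_model"))
  lo <- vapply(model$segments, function(s) s$lo, 0)
  hi <- vapply(model$segments, function(s) s$hi, 0)
  out <- rep(NA_real_, length(i))
  for (k in seq_along(model$segments)) {
    s <- model$segments[[k]]
    in_seg <- i > s$lo & i <= s$hi
    ii <- i[in_seg]
    out[in_seg] <- s$coef[1] * ii^2 + s$coef[2] * ii + s$coef[3]
  }
  if (anyNA(out)) {
    stop_beefhsi("pixel index outside model range (%g, %g]",
                 min(lo), max(hi), class = "beefhsi_range_error")
  }
  out
}
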