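#' Black/white reference frames for reflectance calibration
#'
#' `black` is the dark frame (shutter closed, ~0% reflectance), `white` the
#' frame of a uniform reference standard of known reflectance
#' (`white_reflectance`, default 0.30 for the 30% whiteboard standard).
#' Both must share the cube's frame geometry (rows x cols x bands).
#'
#' @param black,white numeric arrays matching the cube geometry.
#' @param white_reflectance scalar in (0, 1].
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(black, white, white_reflectance = 0.30) {
  if (!all(dim(black) == dim(white))) {
    stop_beefhsi("black and white frames differ in shape",
                 class = "beefhsi_shape_error")
  }
  if (!(white_reflectance > 0 && white_reflectance <= 1)) {
    stop_beefhsi("white_reflectance must lie in (0, 1]",
                 class = "beefhsi_value_error")
  }
  structure(list(black = black, white = white,
                 white_reflectance = white_reflectance),
            class = "reference_frames")
}

#' Black/white reflectance calibration
#'
#' Converts raw intensity to reflectance element-wise:
#' `I = (I0 - B) / (W - B) * white_reflectance`. Elements where
#' `W - B <= 0` (dead or saturated detector positions) cannot be calibrated
#' and are masked to `NA`, with the affected element count recorded in
#' `meta$n_masked_invalid_reference`.
#'
#' @param raw a raw-intensity [hypercube] (`meta$calibrated` FALSE).
#' @param refs a [reference_frames] with the same geometry as `raw`.
#' @return A calibrated [hypercube].
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (isTRUE(raw$meta$calibrated)) {
    stop_beefhsi("cube is already flagged calibrated",
                 class = "beefhsi_value_error")
  }
  if (!all(dim(raw$data) == dim(refs$black))) {
    stop_beefhsi("reference frame geometry does not match cube",
                 class = "beefhsi_shape_error")
  }
  denom <- refs$white - refs$black
  bad <- !(denom > 0)
  if (all(bad)) {
    stop_beefhsi("all reference elements invalid (W - B <= 0 everywhere)",
                 class = "beefhsi_value_error")
  }
  refl <- (raw$data - refs$black) / denom * refs$white_reflectance
  if (any(bad)) refl[bad] <- NA_real_
  meta <- raw$meta
  meta$calibrated <- TRUE
  meta$white_reflectance <- refs$white_reflectance
  meta$n_masked_invalid_reference <- sum(bad)
  hypercube(refl, raw$wavelengths, meta)
}
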