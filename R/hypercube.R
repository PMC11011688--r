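#' Hypercube: a calibrated or raw hyperspectral reflectance cube
#'
#' The central measurement object: a 3-D array with two spatial axes
#' (row, column; origin top-left, 0-based pixel coordinates in metadata
#' conventions, 1-based array indexing as usual in R) and one spectral axis
#' (last). `wavelengths` holds the band-center wavelengths in nm and is
#' stored ascending; cubes whose source stores wavelength decreasing (as
#' push-broom detectors often do) are normalized on construction and the
#' applied permutation recorded in `meta$band_order_reversed`.
#'
#' @param data numeric 3-D array, dimensions (rows, cols, bands).
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   monotone, length `dim(data)[3]`.
#' @param meta named list of free-form acquisition metadata. The flag
#'   `meta$calibrated` marks reflectance (TRUE) versus raw intensity (FALSE).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_beefhsi("`data` must be a 3-D array (rows, cols, bands)",
                 class = "beefhsi_shape_error")
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3]) {
    stop_beefhsi("wavelength count (%d) != band count (%d)",
                 length(wavelengths), dim(data)[3],
                 class = "beefhsi_shape_error")
  }
  d <- diff(wavelengths)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop_beefhsi("wavelengths must be strictly monotone",
                 class = "beefhsi_wavelength_error")
  }
  if (length(d) && all(d < 0)) {
    data <- data[, , rev(seq_along(wavelengths)), drop = FALSE]
    wavelengths <- rev(wavelengths)
    meta$band_order_reversed <- TRUE
  }
  meta$calibrated <- isTRUE(meta$calibrated)
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
    if (isTRUE(x$meta$calibrated)) "calibrated reflectance" else "raw intensity"))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3]
n_pixels <- function(cube) prod(dim(cube$data)[1:2])

# Flatten a cube to a (pixels x bands) matrix, pixels in column-major
# (row-fastest) order matching R's array layout.
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Mean spectrum over a pixel mask
#'
#' Per-band arithmetic mean of the spectra of the masked pixels.
#'
#' @param cube a [hypercube].
#' @param mask logical matrix of the cube's spatial dimensions (`TRUE` =
#'   include), or an integer vector of flattened pixel indices.
#' @return numeric vector of length `n_bands`.
#' @export
mean_spectrum <- function(cube, mask) {
  if (is.logical(mask)) {
    if (!all(dim(mask) == dim(cube$data)[1:2])) {
      stop_beefhsi("mask geometry does not match cube frame",
                   class = "beefhsi_shape_error")
    }
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
  }
  if (length(idx) == 0L) {
    stop_beefhsi("mask selects no pixels", class = "beefhsi_empty_mask_error")
  }
  X <- cube_matrix(cube)[idx, , drop = FALSE]
  colMeans(X)
}
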