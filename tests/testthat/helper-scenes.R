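# Small fixtures shared across test files. Everything is generated in code.

# a fast low-resolution scene configuration
small_config <- function(..., shape = c(16L, 16L), n_bands = 60L, seed = 7L) {
  scene_config(shape = shape, n_bands = n_bands, seed = seed, ...)
}

# a fully noiseless configuration: pixels reproduce endmembers exactly
noiseless_config <- function(..., seed = 7L) {
  small_config(noise_sd = 0, scatter_sd = 0, scene_gain_sd = 0,
               drift_amplitude = 0, band_noise_sd = 0, edge_noise_sd = 0,
               class_jitter_sd = 0, depth_jitter = 0, seed = seed, ...)
}

# fraction of wavelengths within +/- 15 nm of a generator feature center
frac_near_features <- function(wavelengths) {
  mean(vapply(wavelengths, function(w)
    any(abs(w - feature_band_centers()) <= 15), TRUE))
}

# tiny calibrated cube with prescribed per-pixel spectra
cube_from_spectra <- function(spectra_matrix, nr, nc, wavelengths) {
  stopifnot(nrow(spectra_matrix) == nr * nc)
  hypercube(array(spectra_matrix, c(nr, nc, length(wavelengths))),
            wavelengths, list(calibrated = TRUE))
}
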