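#' Pixel-wise deterioration index
#'
#' Scores every non-background pixel on the continuous freshness scale
#' [1, 4] (1 = fresh ... 4 = five freeze-thaw cycles) using the
#' tissue-specific PLS-DA regression scores: muscle pixels through the
#' muscle model on its selected wavelength subset, fat pixels through the
#' fat model on its subset. Pixel spectra are first passed through the same
#' preprocessing pipeline as the training spectra. Scores are clipped to
#' [1, 4]; the raw unclipped scores are kept in `raw_index` for
#' diagnostics. Background pixels carry `NA`.
#'
#' @param cube a calibrated [hypercube].
#' @param mask tissue label matrix (0 background, 1 muscle, 2 fat).
#' @param models named list (`muscle`, `fat`) of `plsda_model`s trained on
#'   the tissue-specific selected wavelength subsets.
#' @param selections named list (`muscle`, `fat`) of `cars_result`s (or
#'   plain index vectors) giving each model's wavelength subset; NULL means
#'   all bands.
#' @param spec the [preprocess_spec] used for the training spectra.
#' @return A `deterioration_map`: `index` (matrix, clipped), `raw_index`,
#'   `mask`.
#' @export
pixel_deterioration <- function(cube, mask, models, selections = NULL,
                                spec = preprocess_spec("RAW")) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  X <- cube_matrix(cube)
  pp <- apply_pipeline(X, cube$wavelengths, spec)
  idx <- matrix(NA_real_, d[1], d[2])
  raw <- matrix(NA_real_, d[1], d[2])
  for (k in c("muscle", "fat")) {
    code <- if (k == "muscle") 1L else 2L
    px <- which(mask == code)
    if (!length(px)) next
    model <- models[[k]]
    if (is.null(model)) {
      stop_beefhsi("no model supplied for tissue '%s'", k,
                   class = "beefhsi_value_error")
    }
    cols <- selections[[k]]
    if (inherits(cols, "cars_result")) cols <- cols$selected_indices
    cols <- cols %||% seq_len(ncol(pp$X))
    if (length(cols) != model$n_features) {
      stop_beefhsi("selection for '%s' has %d bands but model expects %d",
                   k, length(cols), model$n_features,
                   class = "beefhsi_shape_error")
    }
    score <- assign_plsda(model, pp$X[px, cols, drop = FALSE])$score
    raw[px] <- score
    idx[px] <- pmin(4, pmax(1, score))
  }
  structure(list(index = idx, raw_index = raw, mask = mask),
            class = "deterioration_map")
}

# parula-like anchors: dark blue through green to yellow
deterioration_palette <- function() {
  c("#352A87", "#0F5CDD", "#1481D6", "#06A4CA", "#2EB7A4",
    "#87BF77", "#D1BB59", "#FEC832", "#F9FB0E")
}

#' Render a deterioration map as an RGB image
#'
#' Indices are mapped through a fixed blue-to-yellow colormap anchored at
#' 1 (blue) and 4 (yellow); background pixels are painted dark blue.
#'
#' @param map a `deterioration_map`.
#' @param background RGB of background pixels (dark blue).
#' @return numeric array (rows x cols x 3) of RGB values in [0, 1].
#' @export
render_map <- function(map, background = c(0, 0, 0.4)) {
  stopifnot(inherits(map, "deterioration_map"))
  ramp <- grDevices::colorRamp(deterioration_palette(), space = "rgb")
  idx <- map$index
  d <- dim(idx)
  img <- array(rep(background, each = prod(d)), c(d, 3))
  fg <- which(!is.na(idx))
  if (length(fg)) {
    u <- (idx[fg] - 1) / 3
    rgb <- ramp(u) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fg] <- rgb[, ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Write a deterioration map (or a tissue mask) as a PNG file
#'
#' @param map a `deterioration_map` or an integer tissue mask matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path) {
  if (inherits(map, "deterioration_map")) {
    png::writePNG(render_map(map), path)
  } else {
    pal <- matrix(c(0, 0, 0.4,      # background
                    0.55, 0.13, 0.13,  # muscle
                    1, 0.92, 0.8),  # fat
                  3, 3, byrow = TRUE)
    d <- dim(map)
    img <- array(0, c(d, 3))
    for (ch in 1:3) img[, , ch] <- matrix(pal[map + 1L, ch], d[1], d[2])
    png::writePNG(img, path)
  }
  invisible(path)
}
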