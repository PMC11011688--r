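#' Spectral modeling dataset
#'
#' The samples x wavelengths table the classifiers and the wavelength
#' selector operate on: one row per extracted region spectrum, with its
#' freshness class and tissue tag.
#'
#' @param X numeric matrix (samples x wavelengths), no missing values.
#' @param y class labels, a subset of [freshness_classes()].
#' @param tissue per-row tag in `c("muscle", "fat", "cut")`.
#' @param wavelengths band identities of the columns (nm).
#' @param sample_id optional per-row scene/sample identifier.
#' @return A `spectral_dataset` object.
#' @export
spectral_dataset <- function(X, y, tissue, wavelengths,
                             sample_id = seq_len(nrow(X))) {
  X <- as.matrix(X)
  if (anyNA(X)) {
    stop_beefhsi("spectral_dataset: X contains missing values",
                 class = "beefhsi_value_error")
  }
  stopifnot(nrow(X) == length(y), nrow(X) == length(tissue),
            ncol(X) == length(wavelengths))
  class_code(y)  # validates labels
  if (!all(tissue %in% c("muscle", "fat", "cut"))) {
    stop_beefhsi("tissue tags must be muscle/fat/cut",
                 class = "beefhsi_value_error")
  }
  structure(list(X = X, y = y, tissue = tissue,
                 wavelengths = as.numeric(wavelengths),
                 sample_id = sample_id),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d bands; classes: %s; tissues: %s\n",
              nrow(x$X), ncol(x$X),
              paste(names(table(x$y)), table(x$y), sep = ":", collapse = " "),
              paste(unique(x$tissue), collapse = "/")))
  invisible(x)
}

subset_dataset <- function(ds, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(ds$X))
  cols <- cols %||% seq_len(ncol(ds$X))
  spectral_dataset(ds$X[rows, cols, drop = FALSE], ds$y[rows],
                   ds$tissue[rows], ds$wavelengths[cols],
                   ds$sample_id[rows])
}

#' Extract a modeling dataset from generated or measured scenes
#'
#' For every scene, calibrates the raw cube, takes the tissue mask
#' (segmenting against supplied standards when `segment_with` is given,
#' otherwise using the scene's own mask), extracts the ROI mean spectra and
#' optionally preprocesses them.
#'
#' @param scenes list of scenes as from [make_dataset()].
#' @param spec a [preprocess_spec] or preset name applied to the extracted
#'   mean spectra.
#' @param segment_with optional [standard_spectra]; when supplied the mask
#'   is recomputed by [segment()] instead of using the generating mask.
#' @return list with `tissue` (a `spectral_dataset` of muscle and fat rows),
#'   `cut` (a `spectral_dataset` of whole-cut mean rows), and `area`
#'   (data.frame sample_id, class, fat_fraction of cut area).
#' @export
extract_spectra <- function(scenes, spec = preprocess_spec("RAW"),
                            segment_with = NULL) {
  n <- length(scenes)
  wl <- scenes[[1]]$raw$wavelengths
  mus <- fat <- cut <- matrix(NA_real_, n, length(wl))
  has_fat <- logical(n)
  cls <- character(n)
  fat_frac <- numeric(n)
  for (i in seq_len(n)) {
    sc <- scenes[[i]]
    cube <- calibrate_reflectance(sc$raw, sc$refs)
    mask <- if (is.null(segment_with)) sc$mask else {
      segment(cube, segment_with, background_mask = sc$mask == 0L)
    }
    roi <- roi_mean_spectra(cube, mask)
    mus[i, ] <- roi$muscle
    cut[i, ] <- roi$cut
    has_fat[i] <- !is.null(roi$fat)
    if (has_fat[i]) fat[i, ] <- roi$fat
    cls[i] <- sc$class_label %||% sc$config$class_label
    fat_frac[i] <- roi$n_fat / (roi$n_muscle + roi$n_fat)
  }
  pp_mus <- apply_pipeline(mus, wl, spec)
  pp_cut <- apply_pipeline(cut, wl, spec)
  rows_f <- which(has_fat)
  pp_fat <- apply_pipeline(fat[rows_f, , drop = FALSE], wl, spec)
  tissue_ds <- spectral_dataset(
    rbind(pp_mus$X, pp_fat$X),
    c(cls, cls[rows_f]),
    c(rep("muscle", n), rep("fat", length(rows_f))),
    pp_mus$wavelengths,
    sample_id = c(seq_len(n), rows_f))
  cut_ds <- spectral_dataset(pp_cut$X, cls, rep("cut", n),
                             pp_cut$wavelengths, sample_id = seq_len(n))
  list(tissue = tissue_ds, cut = cut_ds,
       area = data.frame(sample_id = seq_len(n), class = cls,
                         fat_fraction = fat_frac))
}
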