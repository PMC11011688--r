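#' Read a hypercube from disk
#'
#' Supports two on-disk forms: an ENVI header+binary pair (`.hdr` beside the
#' binary; BSQ/BIL/BIP interleaves, float32/float64, either byte order) and
#' the package's portable single-file container, which also carries
#' reference frames and a tissue mask when present.
#'
#' @param path path to the container file, the ENVI binary, or the ENVI
#'   `.hdr` header.
#' @return A list with elements `cube` (a [hypercube]), `refs` (a
#'   [reference_frames] or `NULL`) and `mask` (matrix or `NULL`).
#' @export
read_cube <- function(path) {
  if (grepl("\\.hdr$", path) || file.exists(paste0(path, ".hdr"))) {
    read_cube_envi(path)
  } else {
    read_cube_container(path)
  }
}

#' Write a hypercube to disk
#'
#' @param cube a [hypercube].
#' @param path output path. For ENVI this is the binary path; the header is
#'   written beside it as `<path>.hdr`.
#' @param format `"container"` (default) or `"envi"`.
#' @param refs optional [reference_frames] stored alongside (container only).
#' @param mask optional tissue mask matrix stored alongside (container only).
#' @param interleave ENVI interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param dtype storage element type: `"float64"` (lossless) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("container", "envi"),
                       refs = NULL, mask = NULL,
                       interleave = c("bsq", "bil", "bip"),
                       dtype = c("float64", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "hypercube"))
  if (format == "container") {
    obj <- list(
      data = cube$data,
      wavelengths = cube$wavelengths,
      meta = cube$meta,
      refs = if (!is.null(refs)) {
        list(black = refs$black, white = refs$white,
             white_reflectance = refs$white_reflectance)
      },
      mask = mask
    )
    saveRDS(obj, path)
  } else {
    write_cube_envi(cube, path, match.arg(interleave), match.arg(dtype))
  }
  invisible(path)
}

read_cube_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop_beefhsi("not a readable cube container: %s", path,
                 class = "beefhsi_format_error")
  })
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$wavelengths)) {
    stop_beefhsi("container missing field 'data' or 'wavelengths'",
                 class = "beefhsi_format_error")
  }
  refs <- NULL
  if (!is.null(obj$refs)) {
    refs <- reference_frames(obj$refs$black, obj$refs$white,
                             obj$refs$white_reflectance %||% 0.30)
  }
  list(cube = hypercube(obj$data, obj$wavelengths, obj$meta %||% list()),
       refs = refs, mask = obj$mask)
}

# ---- ENVI ------------------------------------------------------------------

envi_dtype_code <- c(float32 = 4L, float64 = 5L)
envi_dtype_size <- c(`4` = 4L, `5` = 8L)

write_cube_envi <- function(cube, path, interleave, dtype) {
  d <- dim(cube$data)
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),   # sample, line, band
    bil = aperm(cube$data, c(2, 3, 1)),   # sample, band, line
    bip = aperm(cube$data, c(3, 2, 1)))   # band, sample, line
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(arr), con,
           size = if (dtype == "float32") 4L else 8L, endian = "little")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    sprintf("data type = %d", envi_dtype_code[[dtype]]),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  # fold multi-line { ... } groups onto one line
  m0 <- gregexpr("\\{[^}]*\\}", txt)[[1]]
  if (m0[1] != -1) {
    regmatches(txt, gregexpr("\\{[^}]*\\}", txt)) <-
      list(gsub("\n", " ", regmatches(txt, gregexpr("\\{[^}]*\\}", txt))[[1]]))
  }
  fields <- list()
  # match key = value where value may be a brace group spanning lines
  pat <- "(?m)^\\s*([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- m
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      piece <- substr(txt, starts[k], starts[k] + lens[k] - 1L)
      key <- tolower(trimws(sub("=.*$", "", piece)))
      val <- trimws(sub("^[^=]*=", "", piece))
      fields[[key]] <- val
    }
  }
  fields
}

read_cube_envi <- function(path) {
  if (grepl("\\.hdr$", path)) {
    hdr_path <- path
    bin_path <- sub("\\.hdr$", "", path)
  } else {
    hdr_path <- paste0(path, ".hdr")
    bin_path <- path
  }
  if (!file.exists(hdr_path)) {
    stop_beefhsi("ENVI header not found: %s", hdr_path,
                 class = "beefhsi_format_error")
  }
  f <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(f))
  if (length(missing)) {
    stop_beefhsi("ENVI header missing field(s): %s",
                 paste(missing, collapse = ", "),
                 class = "beefhsi_format_error")
  }
  samples <- as.integer(f$samples); lines_ <- as.integer(f$lines)
  bands <- as.integer(f$bands)
  dtype <- as.character(as.integer(f[["data type"]]))
  if (!dtype %in% names(envi_dtype_size)) {
    stop_beefhsi("unsupported ENVI data type: %s", dtype,
                 class = "beefhsi_format_error")
  }
  interleave <- tolower(f$interleave)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop_beefhsi("unsupported interleave '%s'", interleave,
                 class = "beefhsi_format_error")
  }
  endian <- if (!is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) == 1L)
    "big" else "little"
  n <- samples * lines_ * bands
  size <- envi_dtype_size[[dtype]]
  expected_bytes <- as.numeric(n) * size
  actual_bytes <- file.info(bin_path)$size
  if (is.na(actual_bytes) || actual_bytes < expected_bytes) {
    stop_beefhsi("ENVI binary truncated: need %.0f bytes, found %.0f",
                 expected_bytes, actual_bytes %||% 0,
                 class = "beefhsi_format_error")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = "double", n = n, size = size, endian = endian)
  data <- switch(interleave,
    bsq = aperm(array(vec, c(samples, lines_, bands)), c(2, 1, 3)),
    bil = aperm(array(vec, c(samples, bands, lines_)), c(3, 1, 2)),
    bip = aperm(array(vec, c(bands, samples, lines_)), c(3, 2, 1)))
  wl <- if (!is.null(f$wavelength)) {
    as.numeric(strsplit(gsub("[{}]", "", f$wavelength), ",")[[1]])
  } else {
    stop_beefhsi("ENVI header missing field(s): wavelength",
                 class = "beefhsi_format_error")
  }
  if (length(wl) != bands) {
    stop_beefhsi("ENVI wavelength count (%d) != bands (%d)",
                 length(wl), bands, class = "beefhsi_format_error")
  }
  list(cube = hypercube(data, wl, list(calibrated = FALSE, source = bin_path)),
       refs = NULL, mask = NULL)
}

# ---- single-spectrum CSV ---------------------------------------------------

#' Read/write a single spectrum as a two-column CSV
#'
#' Columns are `wavelength_nm` and `reflectance`.
#'
#' @param path CSV path.
#' @return `read_spectrum_csv`: a data.frame with those two columns.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "reflectance") %in% names(df))) {
    stop_beefhsi("spectrum CSV must have columns wavelength_nm, reflectance",
                 class = "beefhsi_format_error")
  }
  df[, c("wavelength_nm", "reflectance")]
}

#' @rdname read_spectrum_csv
#' @param wavelengths,reflectance numeric vectors of equal length.
#' @export
write_spectrum_csv <- function(wavelengths, reflectance, path) {
  assert_spectrum_pair(wavelengths, reflectance)
  utils::write.csv(
    data.frame(wavelength_nm = wavelengths, reflectance = reflectance),
    path, row.names = FALSE)
  invisible(path)
}

#' Interpolate a measured spectrum onto a cube's band grid
#'
#' Standards measured on a spectrometer rarely share the imaging system's
#' band centers; linear interpolation resamples them.
#'
#' @param spectrum data.frame with `wavelength_nm`, `reflectance`.
#' @param wavelengths target band grid (nm).
#' @return numeric vector on the target grid.
#' @export
resample_spectrum <- function(spectrum, wavelengths) {
  stats::approx(spectrum$wavelength_nm, spectrum$reflectance,
                xout = wavelengths, rule = 2)$y
}
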