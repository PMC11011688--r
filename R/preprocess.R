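#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum value by the local least-squares polynomial fit
#' over a sliding window. Interior points use the symmetric window; at the
#' edges the polynomial is fit on the truncated one-sided window, so the
#' band count is preserved.
#'
#' @param X spectra matrix (rows = samples, columns = bands) or a vector.
#' @param window odd window length (default 5).
#' @param polyorder polynomial order, `< window` (default 2).
#' @return matrix of the same shape.
#' @export
savitzky_golay <- function(X, window = 5L, polyorder = 2L) {
  if (window %% 2L != 1L || polyorder >= window) {
    stop_beefhsi("need odd window and polyorder < window",
                 class = "beefhsi_value_error")
  }
  vec <- is.null(dim(X))
  X <- rbind(X)
  p <- ncol(X)
  if (window > p) {
    stop_beefhsi("window (%d) exceeds band count (%d)", window, p,
                 class = "beefhsi_value_error")
  }
  h <- (window - 1L) %/% 2L
  # precompute the smoothing weights for every window geometry:
  # weight row = e1' (A'A)^{-1} A' where A is the local Vandermonde
  sg_weights <- function(offsets, at) {
    A <- outer(offsets, 0:polyorder, `^`)
    a <- outer(at, 0:polyorder, `^`)
    drop(a %*% solve(crossprod(A), t(A)))
  }
  W <- matrix(0, p, p)
  interior <- sg_weights(-h:h, 0)
  for (j in seq_len(p)) {
    lo <- max(1L, j - h); hi <- min(p, j + h)
    if (hi - lo + 1L == window) {
      W[j, lo:hi] <- interior
    } else {
      W[j, lo:hi] <- sg_weights((lo:hi) - j, 0)
    }
  }
  out <- X %*% t(W)
  if (vec) drop(out) else out
}

#' First derivative of spectra
#'
#' Forward difference divided by the wavelength step:
#' `(R[j+1] - R[j]) / (wl[j+1] - wl[j])`. The output has one band fewer
#' than the input (251 bands become 250); the associated wavelength grid is
#' the interval midpoints.
#'
#' @param X spectra matrix or vector.
#' @param wavelengths band grid in nm, length `ncol(X)`.
#' @return list with `X` (derivative spectra) and `wavelengths`
#'   (midpoints, length `ncol(X) - 1`).
#' @export
first_derivative <- function(X, wavelengths) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  p <- ncol(X)
  if (p < 2L) {
    stop_beefhsi("first derivative needs >= 2 bands",
                 class = "beefhsi_value_error")
  }
  if (length(wavelengths) != p) {
    stop_beefhsi("wavelength length != band count",
                 class = "beefhsi_shape_error")
  }
  dl <- diff(wavelengths)
  D <- sweep(X[, -1L, drop = FALSE] - X[, -p, drop = FALSE], 2, dl, "/")
  wl_mid <- (wavelengths[-1L] + wavelengths[-p]) / 2
  list(X = if (vec) drop(D) else D, wavelengths = wl_mid)
}

#' Standard normal variate
#'
#' Per spectrum: subtract its mean and divide by its sample standard
#' deviation (n-1 denominator). Removes per-spectrum multiplicative scatter
#' and offset. Zero-variance spectra cannot be scaled; they are returned as
#' zeros with a warning.
#'
#' @param X spectra matrix or vector.
#' @return matrix of the same shape.
#' @export
snv <- function(X) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  mu <- rowMeans(X)
  sd_ <- apply(X, 1, stats::sd)
  zero <- sd_ == 0 | !is.finite(sd_)
  if (any(zero)) {
    warning("zero-variance spectra returned as zeros in snv()")
    sd_[zero] <- 1
  }
  out <- (X - mu) / sd_
  out[zero, ] <- 0
  if (vec) drop(out) else out
}

#' Polynomial detrending
#'
#' Per spectrum, subtracts its least-squares polynomial fit of the given
#' degree over wavelength, removing smooth baseline drift.
#'
#' @param X spectra matrix or vector.
#' @param wavelengths band grid, length `ncol(X)`.
#' @param degree polynomial degree (default 2), `< ncol(X)`.
#' @return matrix of the same shape.
#' @export
detrend <- function(X, wavelengths, degree = 2L) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  p <- ncol(X)
  if (degree >= p || degree < 0) {
    stop_beefhsi("detrend degree must satisfy 0 <= degree < band count",
                 class = "beefhsi_value_error")
  }
  if (length(wavelengths) != p) {
    stop_beefhsi("wavelength length != band count",
                 class = "beefhsi_shape_error")
  }
  u <- (wavelengths - mean(wavelengths)) / stats::sd(wavelengths)
  B <- outer(u, 0:degree, `^`)
  # hat matrix applied from the right: residual = X (I - B (B'B)^{-1} B')
  H <- B %*% solve(crossprod(B), t(B))
  out <- X - X %*% t(H)
  if (vec) drop(out) else out
}

#' Preprocessing pipeline specification
#'
#' An ordered list of operator steps. Named presets follow the study's
#' preprocessing grid: `"RAW"` (identity), `"SG_FD"` (Savitzky-Golay then
#' first derivative — the headline pipeline, 251 bands in, 250 out),
#' `"SG_FD_SNV"`, `"SNV_DETREND"`.
#'
#' @param steps list of steps, each `list(op = <"SG"|"FD"|"SNV"|"DETREND">,
#'   params = list(...))`, or a preset name.
#' @return A `preprocess_spec` object.
#' @export
preprocess_spec <- function(steps = "RAW") {
  if (is.character(steps) && length(steps) == 1L) {
    steps <- switch(steps,
      RAW = list(),
      SG_FD = list(list(op = "SG"), list(op = "FD")),
      SG_FD_SNV = list(list(op = "SG"), list(op = "FD"), list(op = "SNV")),
      SNV_DETREND = list(list(op = "SNV"), list(op = "DETREND")),
      stop_beefhsi("unknown preprocessing preset '%s'", steps,
                   class = "beefhsi_value_error"))
  }
  ok <- vapply(steps, function(s) s$op %in% c("SG", "FD", "SNV", "DETREND"),
               TRUE)
  if (!all(ok)) {
    stop_beefhsi("unknown operator in preprocessing spec",
                 class = "beefhsi_value_error")
  }
  structure(list(steps = steps), class = "preprocess_spec")
}

#' Apply a preprocessing pipeline
#'
#' Operators are applied in listed order; the wavelength vector is trimmed
#' consistently when the first derivative shortens the band axis.
#'
#' @param X spectra matrix (rows = samples).
#' @param wavelengths band grid, length `ncol(X)`.
#' @param spec a [preprocess_spec] or preset name.
#' @return list with `X` and `wavelengths` after all steps.
#' @export
apply_pipeline <- function(X, wavelengths, spec = preprocess_spec("RAW")) {
  if (is.character(spec)) spec <- preprocess_spec(spec)
  stopifnot(inherits(spec, "preprocess_spec"))
  X <- rbind(X)
  for (k in seq_along(spec$steps)) {
    s <- spec$steps[[k]]
    prm <- s$params %||% list()
    res <- tryCatch(switch(s$op,
      SG = list(X = savitzky_golay(X, prm$window %||% 5L,
                                   prm$polyorder %||% 2L),
                wavelengths = wavelengths),
      FD = first_derivative(X, wavelengths),
      SNV = list(X = snv(X), wavelengths = wavelengths),
      DETREND = list(X = detrend(X, wavelengths, prm$degree %||% 2L),
                     wavelengths = wavelengths)),
      error = function(e) {
        stop_beefhsi("pipeline step %d (%s) failed: %s", k, s$op,
                     conditionMessage(e), class = "beefhsi_pipeline_error")
      })
    X <- rbind(res$X)
    wavelengths <- res$wavelengths
  }
  list(X = X, wavelengths = wavelengths)
}
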