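#' Freshness classes
#'
#' Class labels in deterioration order: fresh (`F`), frozen-stored 24 h
#' (`F-S`), frozen-thawed three times (`F-T-3`), frozen-thawed five times
#' (`F-T-5`). The ordinal codes 1-4 used throughout modeling follow this
#' order.
#' @export
freshness_classes <- function() c("F", "F-S", "F-T-3", "F-T-5")

class_code <- function(label) {
  code <- match(label, freshness_classes())
  if (anyNA(code)) {
    stop_beefhsi("unknown class label(s): %s",
                 paste(unique(label[is.na(code)]), collapse = ", "),
                 class = "beefhsi_value_error")
  }
  code
}

#' Scene configuration for the synthetic beef-cut generator
#'
#' Defaults are the package's study conditions: 64x64-pixel scenes on a
#' 251-band grid over 400-800 nm, 30% areal fat fraction. Noise model,
#' per scene: latent deterioration state `t = class_code + N(0,
#' class_jitter_sd)`; absorption-depth jitter (`depth_jitter`, relative);
#' illumination gain `1 + N(0, scene_gain_sd)`; band-wise spectral-response
#' noise whose sd is `band_noise_sd` in the mid-range and rises by
#' `edge_noise_sd` toward the spectral edges (below ~405 nm and above
#' ~700 nm), where halogen output and detector quantum efficiency fall off.
#' Per pixel: multiplicative scatter `1 + N(0, scatter_sd)`, a random
#' quadratic baseline of amplitude `drift_amplitude`, and additive Gaussian
#' noise `noise_sd`.
#'
#' @param shape integer c(rows, cols).
#' @param n_bands band count (default 251).
#' @param band_range wavelength interval in nm (default c(400, 800)).
#' @param fat_fraction target areal fat fraction within the cut, in (0, 1).
#' @param class_label one of [freshness_classes()].
#' @param noise_sd per-pixel additive noise sd (reflectance units).
#' @param scatter_sd per-pixel multiplicative gain sd.
#' @param scene_gain_sd per-scene illumination gain sd.
#' @param drift_amplitude per-pixel quadratic baseline amplitude.
#' @param band_noise_sd per-scene mid-range spectral-response noise sd.
#' @param edge_noise_sd additional band noise sd at the spectral edges.
#' @param class_jitter_sd sd of the latent deterioration state around the
#'   class code (biological within-class variability).
#' @param depth_jitter relative per-scene jitter of absorption-feature
#'   depths.
#' @param effect_scale global knob on class separation (1 = default
#'   conditions, 0 = classes identical).
#' @param seed integer seed; same seed + config gives identical output.
#' @return A `scene_config` list.
#' @export
scene_config <- function(shape = c(64L, 64L), n_bands = 251L,
                         band_range = c(400, 800), fat_fraction = 0.30,
                         class_label = "F", noise_sd = 0.005,
                         scatter_sd = 0.02, scene_gain_sd = 0.02,
                         drift_amplitude = 0.01, band_noise_sd = 0.004,
                         edge_noise_sd = 0.04, class_jitter_sd = 0.10,
                         depth_jitter = 0.02, effect_scale = 1,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8L),
            n_bands >= 2L, band_range[2] > band_range[1])
  if (!(fat_fraction > 0 && fat_fraction < 1)) {
    stop_beefhsi("fat_fraction must lie in (0, 1)",
                 class = "beefhsi_value_error")
  }
  nonneg <- c(noise_sd, scatter_sd, scene_gain_sd, drift_amplitude,
              band_noise_sd, edge_noise_sd, class_jitter_sd, depth_jitter,
              effect_scale)
  if (any(nonneg < 0)) {
    stop_beefhsi("noise/scatter/drift/effect parameters must be >= 0",
                 class = "beefhsi_value_error")
  }
  class_label <- match.arg(class_label, freshness_classes())
  structure(list(shape = as.integer(shape), n_bands = as.integer(n_bands),
                 band_range = band_range, fat_fraction = fat_fraction,
                 class_label = class_label, noise_sd = noise_sd,
                 scatter_sd = scatter_sd, scene_gain_sd = scene_gain_sd,
                 drift_amplitude = drift_amplitude,
                 band_noise_sd = band_noise_sd,
                 edge_noise_sd = edge_noise_sd,
                 class_jitter_sd = class_jitter_sd,
                 depth_jitter = depth_jitter,
                 effect_scale = effect_scale, seed = as.integer(seed)),
            class = "scene_config")
}

band_grid <- function(config) {
  seq(config$band_range[1], config$band_range[2], length.out = config$n_bands)
}

# Gaussian absorption dip; width is quoted as FWHM (the spectroscopic
# convention), so sigma = width / (2 sqrt(2 ln 2)).
gaussian_dip <- function(wl, center, width, depth) {
  depth * exp(-0.5 * ((wl - center) / (width / 2.3548200450309493))^2)
}

# wavelength-dependent sensor noise sd: quiet mid-range, noisy edges
band_noise_profile <- function(wl, base_sd, edge_sd) {
  base_sd + edge_sd * (1 / (1 + exp((wl - 405) / 4)) +
                       1 / (1 + exp(-(wl - 700) / 10)))
}

#' Class-wise muscle and fat endmember spectra
#'
#' Builds the spectral library the generator draws from. Muscle and fat
#' baselines are smooth sigmoids rising toward the red/NIR, fat well above
#' the pigment-rich muscle everywhere. Heme-pigment absorption dips sit at
#' 420 nm (Soret, FWHM 15 nm) and the 550/572 nm oxymyoglobin doublet
#' (FWHM 20 nm), much deeper in muscle than fat (depth weight 0.25).
#' Freeze-thaw processing deepens the absorption features monotonically
#' with the deterioration state t (1 = fresh ... 4 = five cycles):
#' pigment dips grow by per-unit factors (0.10, 0.35, 0.35) for
#' 420/550/572 nm (metmyoglobin formation hits the oxymyoglobin doublet
#' hardest, and drip loss concentrates pigments at the surface), oxidation
#' dips at 500/650 nm (FWHM 20 nm, weight 0.5 in fat) deepen by 0.01
#' reflectance per unit, and a mild global reflectance scale
#' `1 - 0.005 (t - 1)` accounts for dehydration. `effect_scale` scales all
#' departures from the fresh state; at 0 the classes coincide.
#'
#' @param wavelengths band grid in nm (default 251 bands on 400-800).
#' @param effect_scale nonnegative class-separation knob.
#' @return An `endmember_library`: `muscle_by_class` and `fat_by_class`
#'   (named lists of spectra at the integer class states), `wavelengths`,
#'   `band_features` (data.frame of the Gaussian components), and the
#'   continuous generator `spectrum_fun(tissue, t, depth_factors)`.
#' @export
make_endmembers <- function(wavelengths = seq(400, 800, length.out = 251),
                            effect_scale = 1) {
  stopifnot(effect_scale >= 0)
  wl <- wavelengths
  muscle_base <- 0.16 + 0.24 / (1 + exp(-(wl - 600) / 45))
  fat_base    <- 0.46 + 0.16 / (1 + exp(-(wl - 560) / 55))
  pigment <- data.frame(center = c(420, 550, 572),
                        width = c(15, 20, 20),
                        depth = c(0.080, 0.050, 0.045),
                        deepen = c(0.10, 0.35, 0.35))
  oxidation <- data.frame(center = c(500, 650), width = c(20, 20),
                          deepen = c(0.01, 0.01))
  spectrum_fun <- function(tissue = c("muscle", "fat"), t,
                           depth_factors = rep(1, 5)) {
    tissue <- match.arg(tissue)
    dt <- effect_scale * (t - 1)
    pig_w <- if (tissue == "muscle") 1 else 0.25
    ox_w <- if (tissue == "muscle") 1 else 0.5
    base <- if (tissue == "muscle") muscle_base else fat_base
    dips <- rowSums(mapply(function(c0, w, d, dp, j)
      gaussian_dip(wl, c0, w, d * pig_w * (1 + dp * dt) * j),
      pigment$center, pigment$width, pigment$depth, pigment$deepen,
      depth_factors[1:3]))
    ox <- rowSums(mapply(function(c0, w, dp, j)
      gaussian_dip(wl, c0, w, dp * dt * ox_w * j),
      oxidation$center, oxidation$width, oxidation$deepen,
      depth_factors[4:5]))
    (1 - 0.005 * dt) * (base - dips - ox)
  }
  classes <- freshness_classes()
  muscle <- lapply(1:4, function(k) spectrum_fun("muscle", k))
  fat <- lapply(1:4, function(k) spectrum_fun("fat", k))
  names(muscle) <- names(fat) <- classes
  features <- rbind(
    cbind(pigment, role = "pigment"),
    cbind(oxidation, depth = NA_real_, role = "oxidation")[,
      c("center", "width", "depth", "deepen", "role")])
  structure(list(muscle_by_class = muscle, fat_by_class = fat,
                 wavelengths = wl, band_features = features,
                 spectrum_fun = spectrum_fun,
                 effect_scale = effect_scale),
            class = "endmember_library")
}

#' Feature band centers of the generator
#'
#' The five wavelength centers (nm) where the generator concentrates
#' class-discriminative structure: heme pigments at 420/550/572 nm,
#' oxidation at 500/650 nm.
#' @export
feature_band_centers <- function() c(420, 500, 550, 572, 650)

# Memoized black/white detector frames for a given scene geometry.
frames_cache <- new.env(parent = emptyenv())
detector_frames <- function(nr, nc, wl) {
  key <- paste(nr, nc, length(wl), wl[1], wl[length(wl)], sep = "_")
  if (!is.null(frames_cache[[key]])) return(frames_cache[[key]])
  npx <- nr * nc
  nb <- length(wl)
  black <- array(rep(100, npx * nb), c(nr, nc, nb))
  illum <- 3000 + 800 * exp(-0.5 * ((wl - 620) / 160)^2)
  white <- black + array(rep(illum, each = npx), c(nr, nc, nb))
  frames_cache[[key]] <- list(black = black, white = white)
  frames_cache[[key]]
}

# Separable Gaussian blur of a matrix (reflected edges).
blur_matrix <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1L]))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

#' Generate a marbled tissue mask
#'
#' An elliptical cut region on a background, with connected fat blobs
#' (smoothed-noise field thresholded at the quantile matching
#' `fat_fraction`) on muscle. Labels: 0 background, 1 muscle, 2 fat.
#'
#' @param config a [scene_config].
#' @return integer matrix of labels with attribute `levels`
#'   `c("background", "muscle", "fat")`.
#' @export
make_tissue_mask <- function(config) {
  with_seed(config$seed, {
    nr <- config$shape[1]; nc <- config$shape[2]
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    inside <- ((rr - (nr + 1) / 2) / (0.42 * nr))^2 +
              ((cc - (nc + 1) / 2) / (0.42 * nc))^2 <= 1
    field <- blur_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                         sigma = max(2, round(min(nr, nc) / 16)))
    thr <- stats::quantile(field[inside], probs = 1 - config$fat_fraction)
    labels <- matrix(0L, nr, nc)
    labels[inside] <- 1L
    labels[inside & field > thr] <- 2L
    attr(labels, "levels") <- c("background", "muscle", "fat")
    labels
  })
}

#' Generate one synthetic beef-cut scene
#'
#' Draws the scene-level state (latent deterioration `t`, feature-depth
#' jitter, illumination gain, band-wise sensor noise), builds the
#' reflectance field pixel by pixel as
#' `gain_scene * gain_pixel * endmember(tissue, t) + drift + band_noise +
#' pixel_noise`, and returns a RAW intensity cube with matching black/white
#' reference frames constructed so that [calibrate_reflectance()] recovers
#' the reflectance field exactly (to floating point). Background pixels
#' carry a near-zero reflectance (0.005). With all noise parameters zero,
#' every muscle pixel equals the class muscle endmember exactly after
#' calibration.
#'
#' @param config a [scene_config].
#' @param lib an `endmember_library` from [make_endmembers()]; built from
#'   the config's band grid and effect scale when omitted.
#' @return list with `raw` (raw [hypercube]), `refs` ([reference_frames]),
#'   `mask` (generating tissue mask), `reflectance` (the intended noisy
#'   reflectance cube, calibrated), `class_label`, `t` (latent state),
#'   `config`.
#' @export
make_cube <- function(config, lib = NULL) {
  wl <- band_grid(config)
  if (is.null(lib)) lib <- make_endmembers(wl, config$effect_scale)
  if (length(lib$wavelengths) != length(wl) ||
      any(abs(lib$wavelengths - wl) > 1e-9)) {
    stop_beefhsi("endmember library grid does not match scene config",
                 class = "beefhsi_shape_error")
  }
  mask <- make_tissue_mask(config)
  nr <- config$shape[1]; nc <- config$shape[2]; nb <- config$n_bands
  npx <- nr * nc
  k <- class_code(config$class_label)
  with_seed(config$seed + 1L, {
    # scene-level draws (order must not depend on class_label)
    t_state <- k + config$class_jitter_sd * stats::rnorm(1L)
    depth_factors <- 1 + config$depth_jitter * stats::rnorm(5L)
    scene_gain <- 1 + config$scene_gain_sd * stats::rnorm(1L)
    sdp <- band_noise_profile(wl, config$band_noise_sd, config$edge_noise_sd)
    band_noise <- sdp * stats::rnorm(nb)
    em_m <- lib$spectrum_fun("muscle", t_state, depth_factors)
    em_f <- lib$spectrum_fun("fat", t_state, depth_factors)
    base <- matrix(0.005, npx, nb)
    mus <- which(mask == 1L); fat <- which(mask == 2L)
    base[mus, ] <- matrix(em_m, length(mus), nb, byrow = TRUE)
    base[fat, ] <- matrix(em_f, length(fat), nb, byrow = TRUE)
    gain <- scene_gain * (1 + config$scatter_sd * stats::rnorm(npx))
    refl <- base * gain
    tissue_px <- c(mus, fat)
    refl[tissue_px, ] <- refl[tissue_px, ] +
      matrix(band_noise, length(tissue_px), nb, byrow = TRUE)
    if (config$drift_amplitude > 0) {
      u <- (wl - min(wl)) / diff(range(wl))
      c0 <- config$drift_amplitude * stats::rnorm(npx)
      c1 <- config$drift_amplitude * stats::rnorm(npx)
      c2 <- config$drift_amplitude * stats::rnorm(npx)
      refl <- refl + outer(c0, rep(1, nb)) + outer(c1, u) + outer(c2, u^2)
    }
    if (config$noise_sd > 0) {
      refl <- refl + config$noise_sd * stats::rnorm(npx * nb)
    }
    refl_cube <- array(refl, c(nr, nc, nb))
    # detector model: B flat dark level, W dark + smooth illumination ramp;
    # frames are deterministic per geometry, so one shared copy serves all
    # scenes of a dataset (R's copy-on-write keeps this cheap)
    frames <- detector_frames(nr, nc, wl)
    black <- frames$black
    white <- frames$white
    raw_arr <- black + refl_cube / 0.30 * (white - black)
    raw <- hypercube(raw_arr, wl,
                     list(calibrated = FALSE, class_label = config$class_label,
                          seed = config$seed))
    refs <- reference_frames(black, white, 0.30)
    intended <- hypercube(refl_cube, wl,
                          list(calibrated = TRUE,
                               class_label = config$class_label))
    list(raw = raw, refs = refs, mask = mask, reflectance = intended,
         class_label = config$class_label, t = t_state, config = config)
  })
}

#' Generate a balanced multi-scene dataset
#'
#' `4 * n_per_class` scenes, one freshness class per group, with per-scene
#' seeds derived deterministically from the master seed and the areal fat
#' fraction jittered uniformly within `fat_range` across scenes.
#'
#' @param n_per_class scenes per class (the study design uses 60).
#' @param config_template a [scene_config] supplying everything but class,
#'   seed and fat fraction.
#' @param seed master seed.
#' @param fat_range uniform jitter interval for the fat fraction.
#' @return list of scene lists as returned by [make_cube()]; attribute
#'   `manifest` is a data.frame (scene_id, class, seed, fat_fraction).
#' @export
make_dataset <- function(n_per_class, config_template = scene_config(),
                         seed = 1L, fat_range = c(0.2, 0.4)) {
  stopifnot(n_per_class >= 1L)
  classes <- rep(freshness_classes(), each = n_per_class)
  n <- length(classes)
  seeds <- derive_seeds(seed, n)
  fats <- with_seed(seed + 7L,
                    stats::runif(n, fat_range[1], fat_range[2]))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config_template
    cfg$class_label <- classes[i]
    cfg$seed <- seeds[i]
    cfg$fat_fraction <- fats[i]
    scenes[[i]] <- make_cube(cfg)
    scenes[[i]]$reflectance <- NULL  # recomputable; keeps datasets compact
  }
  attr(scenes, "manifest") <- data.frame(
    scene_id = seq_len(n), class = classes, seed = seeds,
    fat_fraction = fats)
  scenes
}
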