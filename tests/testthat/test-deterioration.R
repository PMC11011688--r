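# tissue-specific PLS-DA models trained on noiseless endmember spectra
noiseless_models <- function(wavelengths) {
  lib <- make_endmembers(wavelengths)
  y <- freshness_classes()
  list(models = list(
         muscle = fit_plsda(do.call(rbind, lib$muscle_by_class), y),
         fat = fit_plsda(do.call(rbind, lib$fat_by_class), y)),
       lib = lib)
}

test_that("noiseless scenes score their true class index at every pixel", {
  for (cl in c("F", "F-T-5")) {
    cfg <- noiseless_config(class_label = cl, seed = 41L)
    sc <- make_cube(cfg)
    cal <- calibrate_reflectance(sc$raw, sc$refs)
    nm <- noiseless_models(cal$wavelengths)
    dmap <- pixel_deterioration(cal, sc$mask, nm$models)
    k <- match(cl, freshness_classes())
    idx <- dmap$index[!is.na(dmap$index)]
    expect_lt(max(abs(idx - k)), 1e-6)
    expect_true(all(is.na(dmap$index[sc$mask == 0L])))
  }
})

test_that("default-noise F-S scenes recover a class-2 mean index", {
  cfg <- small_config(class_label = "F-S", seed = 42L)
  sc <- make_cube(cfg)
  cal <- calibrate_reflectance(sc$raw, sc$refs)
  nm <- noiseless_models(cal$wavelengths)
  dmap <- pixel_deterioration(cal, sc$mask, nm$models)
  m <- mean(dmap$index, na.rm = TRUE)
  expect_gte(m, 1.5)
  expect_lte(m, 2.5)
})

test_that("indices are clipped to the class scale with raw scores retained", {
  cfg <- noiseless_config(class_label = "F", seed = 43L)
  sc <- make_cube(cfg)
  cal <- calibrate_reflectance(sc$raw, sc$refs)
  nm <- noiseless_models(cal$wavelengths)
  # shift all spectra far below the fresh endmember to force out-of-range
  cal$data <- cal$data - 0.5
  dmap <- pixel_deterioration(cal, sc$mask, nm$models)
  idx <- dmap$index[!is.na(dmap$index)]
  expect_true(all(idx >= 1 & idx <= 4))
  raw <- dmap$raw_index[!is.na(dmap$raw_index)]
  expect_true(any(raw > 4 | raw < 1))
  # mismatched selection length is rejected
  expect_error(pixel_deterioration(cal, sc$mask, nm$models,
                                   selections = list(muscle = 1:3,
                                                     fat = 1:3)),
               class = "beefhsi_shape_error")
})

test_that("rendering anchors the colormap at blue (1) and yellow (4)", {
  idx <- matrix(c(1, 4, 2.5, NA), 2, 2)
  map <- structure(list(index = idx, raw_index = idx,
                        mask = matrix(c(1L, 1L, 1L, 0L), 2, 2)),
                   class = "deterioration_map")
  img <- render_map(map)
  pal <- beefhsi:::deterioration_palette()
  blue <- as.vector(grDevices::col2rgb(pal[1])) / 255
  yellow <- as.vector(grDevices::col2rgb(pal[length(pal)])) / 255
  expect_equal(as.vector(img[1, 1, ]), blue, tolerance = 1e-6)
  expect_equal(as.vector(img[2, 1, ]), yellow, tolerance = 1e-6)
  # background renders dark blue
  expect_equal(as.vector(img[2, 2, ]), c(0, 0, 0.4))
  # blue-to-yellow trend: red rises and blue falls from the 1-anchor to
  # the 4-anchor, and the index-to-ramp-position map is monotone
  ramp <- grDevices::colorRamp(pal)
  ends <- ramp(c(0, 1))
  expect_gt(ends[2, 1], ends[1, 1])   # red grows
  expect_lt(ends[2, 3], ends[1, 3])   # blue shrinks
  u <- (c(1, 2, 3, 4) - 1) / 3
  expect_true(all(diff(u) > 0))
  # files are written
  png_path <- tempfile(fileext = ".png")
  write_map_png(map, png_path)
  expect_true(file.exists(png_path))
  arr <- png::readPNG(png_path)
  expect_equal(dim(arr), c(2, 2, 3))
})

test_that("mean deterioration rises across the class sequence", {
  nm <- NULL
  means <- vapply(freshness_classes(), function(cl) {
    cfg <- small_config(class_label = cl, seed = 44L)
    sc <- make_cube(cfg)
    cal <- calibrate_reflectance(sc$raw, sc$refs)
    if (is.null(nm)) nm <<- noiseless_models(cal$wavelengths)
    dmap <- pixel_deterioration(cal, sc$mask, nm$models)
    mean(dmap$index, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) >= 0))
})
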