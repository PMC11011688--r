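test_that("wavelength model matches direct polynomial evaluation", {
  m <- default_wavelength_model()
  # oracle: evaluate the printed branch polynomials directly
  branch1 <- function(i) -7.37e-06 * i^2 - 0.201 * i + 803.26
  branch2 <- function(i) -2.09e-06 * i^2 - 0.213 * i + 809.19
  expect_equal(evaluate_wavelength_model(m, 100), branch1(100),
               tolerance = 1e-12)
  expect_equal(evaluate_wavelength_model(m, 1000), branch1(1000),
               tolerance = 1e-12)
  expect_equal(evaluate_wavelength_model(m, 1940), branch2(1940),
               tolerance = 1e-12)
  # frozen values computed from the oracle
  expect_equal(evaluate_wavelength_model(m, c(100, 1000, 1940)),
               c(783.0863, 594.89, 388.104076), tolerance = 1e-6)
})

test_that("wavelength model is strictly decreasing with range in [385, 795]", {
  m <- default_wavelength_model()
  i <- seq(51, 1940)
  wl <- evaluate_wavelength_model(m, i)
  expect_true(all(diff(wl) < 0))
  expect_gte(min(wl), 385)
  expect_lte(max(wl), 795)
})

test_that("out-of-range pixel indices raise an informative error", {
  m <- default_wavelength_model()
  expect_error(evaluate_wavelength_model(m, 20), "50",
               class = "beefhsi_range_error")
  expect_error(evaluate_wavelength_model(m, 2000),
               class = "beefhsi_range_error")
})

test_that("reflectance calibration identities hold exactly", {
  set.seed(42)
  d <- c(4L, 5L, 6L)
  B <- array(runif(prod(d), 50, 150), d)
  W <- B + array(runif(prod(d), 400, 900), d)
  refs <- reference_frames(B, W, 0.30)
  cal_w <- calibrate_reflectance(hypercube(W, 1:6, list(calibrated = FALSE)),
                                 refs)
  cal_b <- calibrate_reflectance(hypercube(B, 1:6, list(calibrated = FALSE)),
                                 refs)
  cal_h <- calibrate_reflectance(
    hypercube((W + B) / 2, 1:6, list(calibrated = FALSE)), refs)
  expect_equal(as.vector(cal_w$data), rep(0.30, prod(d)))
  expect_equal(as.vector(cal_b$data), rep(0, prod(d)))
  expect_equal(as.vector(cal_h$data), rep(0.15, prod(d)))
  expect_true(cal_w$meta$calibrated)
})

test_that("calibration is monotone in the raw intensity and masks bad pixels", {
  set.seed(43)
  d <- c(3L, 3L, 4L)
  B <- array(100, d)
  W <- array(600, d)
  W[1, 1, 1] <- 100  # dead element: W - B = 0
  refs <- reference_frames(B, W)
  I1 <- array(runif(prod(d), 100, 600), d)
  I2 <- I1 + array(runif(prod(d), 0, 50), d)
  c1 <- calibrate_reflectance(hypercube(I1, 1:4, list(calibrated = FALSE)), refs)
  c2 <- calibrate_reflectance(hypercube(I2, 1:4, list(calibrated = FALSE)), refs)
  ok <- !is.na(c1$data)
  expect_true(all(c2$data[ok] >= c1$data[ok]))
  expect_true(is.na(c1$data[1, 1, 1]))
  expect_identical(c1$meta$n_masked_invalid_reference, 1L)
  # geometry mismatch and double calibration are rejected
  expect_error(calibrate_reflectance(
    hypercube(array(0, c(2, 2, 4)), 1:4, list(calibrated = FALSE)), refs),
    class = "beefhsi_shape_error")
  expect_error(calibrate_reflectance(c1, refs), class = "beefhsi_value_error")
  expect_error(calibrate_reflectance(
    hypercube(I1, 1:4, list(calibrated = FALSE)),
    reference_frames(B, B)), class = "beefhsi_value_error")
})

test_that("mean_spectrum averages masked pixels per band", {
  wl <- c(500, 510, 520)
  s1 <- c(0.1, 0.2, 0.3); s2 <- c(0.5, 0.6, 0.7)
  cube <- cube_from_spectra(rbind(s1, s2, s1, s2), 2, 2, wl)
  all_mask <- matrix(TRUE, 2, 2)
  expect_equal(mean_spectrum(cube, all_mask), (s1 + s2) / 2)
  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, one), s1)
  uniform <- cube_from_spectra(matrix(0.4, 4, 3), 2, 2, wl)
  expect_equal(mean_spectrum(uniform, all_mask), rep(0.4, 3))
  expect_error(mean_spectrum(cube, matrix(FALSE, 2, 2)),
               class = "beefhsi_empty_mask_error")
})

test_that("descending wavelength cubes are normalized to ascending order", {
  arr <- array(seq_len(24), c(2, 3, 4))
  cube <- hypercube(arr, c(700, 650, 600, 550))
  expect_equal(cube$wavelengths, c(550, 600, 650, 700))
  expect_true(cube$meta$band_order_reversed)
  expect_equal(cube$data[1, 1, ], arr[1, 1, 4:1])
  expect_error(hypercube(arr, c(700, 600, 650, 550)),
               class = "beefhsi_wavelength_error")
  expect_error(hypercube(arr, c(700, 650, 600)),
               class = "beefhsi_shape_error")
})

test_that("ENVI interleaves round-trip identically", {
  set.seed(44)
  cube <- hypercube(array(rnorm(3 * 5 * 7), c(3, 5, 7)),
                    seq(400, 460, 10), list(calibrated = FALSE))
  for (il in c("bsq", "bil", "bip")) {
    path <- tempfile(fileext = ".raw")
    write_cube(cube, path, format = "envi", interleave = il)
    back <- read_cube(path)
    expect_equal(back$cube$data, cube$data, tolerance = 0)
    expect_equal(back$cube$wavelengths, cube$wavelengths)
  }
})

test_that("float32 ENVI storage keeps relative error below 1e-6", {
  set.seed(45)
  cube <- hypercube(array(runif(60, 0.1, 0.9), c(3, 4, 5)), seq(5),
                    list(calibrated = FALSE))
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path, format = "envi", dtype = "float32")
  back <- read_cube(path)
  expect_lt(max(abs(back$cube$data - cube$data) / abs(cube$data)), 1e-6)
})

test_that("malformed ENVI input raises format errors naming the problem", {
  set.seed(46)
  cube <- hypercube(array(rnorm(24), c(2, 3, 4)), 1:4,
                    list(calibrated = FALSE))
  path <- tempfile(fileext = ".raw")
  write_cube(cube, path, format = "envi")
  hdr <- readLines(paste0(path, ".hdr"))
  # wavelength count mismatch
  bad <- sub("wavelength = .*", "wavelength = { 1, 2, 3 }", hdr)
  writeLines(bad, paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelength", class = "beefhsi_format_error")
  # missing required field
  writeLines(hdr[!grepl("^samples", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "samples", class = "beefhsi_format_error")
  # truncated binary
  writeLines(hdr, paste0(path, ".hdr"))
  writeBin(raw(10), path)
  expect_error(read_cube(path), "truncated", class = "beefhsi_format_error")
})

test_that("container round-trip preserves data, metadata, refs and mask", {
  set.seed(47)
  d <- c(4L, 4L, 6L)
  B <- array(100, d); W <- array(500, d)
  cube <- hypercube(array(rnorm(prod(d)), d), seq(400, 450, 10),
                    list(calibrated = FALSE, exposure = "12ms"))
  refs <- reference_frames(B, W, 0.30)
  mask <- matrix(0:1, 4, 4)
  path <- tempfile(fileext = ".bhc")
  write_cube(cube, path, refs = refs, mask = mask)
  back <- read_cube(path)
  expect_identical(back$cube$data, cube$data)
  expect_identical(back$cube$meta$exposure, "12ms")
  expect_identical(back$refs$black, B)
  expect_identical(back$mask, mask)
})

test_that("spectrum CSV round-trips and resamples onto a band grid", {
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(c(400, 500, 600), c(0.1, 0.3, 0.2), path)
  sp <- read_spectrum_csv(path)
  expect_equal(sp$reflectance, c(0.1, 0.3, 0.2))
  expect_equal(resample_spectrum(sp, c(450, 550)), c(0.2, 0.25))
})
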