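test_that("Savitzky-Golay reproduces low-order polynomials and the classic kernel", {
  x <- seq_len(31)
  poly <- 2 + 0.3 * x - 0.01 * x^2
  sm <- savitzky_golay(rbind(poly), window = 5, polyorder = 2)
  expect_lt(max(abs(sm - poly)), 1e-10)
  # impulse response at an interior point gives the 5-point quadratic kernel
  imp <- rep(0, 11); imp[6] <- 1
  resp <- savitzky_golay(rbind(imp), 5, 2)[1, 4:8]
  expect_equal(resp, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  expect_error(savitzky_golay(rbind(poly), window = 4, polyorder = 2),
               class = "beefhsi_value_error")
  expect_error(savitzky_golay(rbind(poly), window = 5, polyorder = 5),
               class = "beefhsi_value_error")
})

test_that("Savitzky-Golay agrees with the signal package kernel and shrinks noise", {
  skip_if_not_installed("signal")
  ks <- signal::sgolay(p = 2, n = 7)
  imp <- rep(0, 15); imp[8] <- 1
  resp <- savitzky_golay(rbind(imp), 7, 2)[1, 5:11]
  expect_equal(resp, as.numeric(ks[4, ]), tolerance = 1e-10)
  set.seed(61)
  X <- matrix(rnorm(1000 * 40), 1000, 40)
  Xs <- savitzky_golay(X, 5, 2)
  expect_lt(mean(apply(Xs[, 3:38], 1, var)), mean(apply(X[, 3:38], 1, var)))
})

test_that("first derivative annihilates constants and recovers slopes", {
  wl <- seq(400, 800, length.out = 251)
  const <- rep(0.4, 251)
  fd <- first_derivative(rbind(const), wl)
  expect_equal(as.vector(fd$X), rep(0, 250))
  lin <- 0.001 * wl
  fd2 <- first_derivative(rbind(lin), wl)
  expect_equal(as.vector(fd2$X), rep(0.001, 250), tolerance = 1e-12)
  expect_length(fd2$wavelengths, 250)
  expect_error(first_derivative(rbind(0.5), 400),
               class = "beefhsi_value_error")
})

test_that("SNV centers and scales each spectrum and ignores affine gain", {
  expect_equal(as.vector(snv(c(1, 2, 3))), c(-1, 0, 1))
  set.seed(62)
  X <- matrix(runif(5 * 30), 5, 30)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_equal(snv(3.7 * X + 0.2), Z, tolerance = 1e-10)
  expect_warning(out <- snv(rbind(rep(1, 10))), "zero-variance")
  expect_equal(as.vector(out), rep(0, 10))
})

test_that("detrend removes polynomial baselines and only those", {
  wl <- seq(400, 800, length.out = 80)
  base <- 0.5 - 0.001 * wl + 2e-6 * wl^2
  expect_lt(max(abs(detrend(rbind(base), wl))), 1e-10)
  set.seed(63)
  sig <- runif(80)
  expect_equal(detrend(rbind(sig + base), wl), detrend(rbind(sig), wl),
               tolerance = 1e-9, ignore_attr = TRUE)
  # residual orthogonal to the polynomial basis
  res <- detrend(rbind(sig), wl)[1, ]
  u <- (wl - mean(wl)) / sd(wl)
  for (pwr in 0:2) expect_lt(abs(sum(res * u^pwr)), 1e-8)
  expect_error(detrend(rbind(sig), wl, degree = 80),
               class = "beefhsi_value_error")
})

test_that("pipelines compose operators in order with consistent wavelengths", {
  set.seed(64)
  X <- matrix(runif(3 * 251), 3, 251)
  wl <- seq(400, 800, length.out = 251)
  ident <- apply_pipeline(X, wl, preprocess_spec("RAW"))
  expect_equal(ident$X, X)
  sgfd <- apply_pipeline(X, wl, preprocess_spec("SG_FD"))
  expect_equal(ncol(sgfd$X), 250)
  expect_length(sgfd$wavelengths, 250)
  expect_equal(apply_pipeline(X, wl, "SG_FD")$X, sgfd$X)
  # row-wise independence: permuting samples permutes outputs
  perm <- c(3, 1, 2)
  expect_equal(apply_pipeline(X[perm, ], wl, "SG_FD_SNV")$X,
               apply_pipeline(X, wl, "SG_FD_SNV")$X[perm, ])
  # errors are tagged with the failing step
  bad <- preprocess_spec(list(list(op = "SG",
                                   params = list(window = 999))))
  expect_error(apply_pipeline(X, wl, bad), "step 1",
               class = "beefhsi_pipeline_error")
  expect_error(preprocess_spec("NOPE"), class = "beefhsi_value_error")
})
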