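test_that("SPXY seeds with the extreme pair and honors the ceiling rule", {
  X <- matrix(0:7, ncol = 1)
  expect_warning(sp <- spxy_split(X, rep(1, 8), 0.75), "zero spread")
  expect_true(all(c(1, 8) %in% sp$train_ids))
  expect_length(sp$train_ids, 6)
  expect_length(sp$test_ids, 2)
  expect_identical(sort(c(sp$train_ids, sp$test_ids)), 1:8)
  # deterministic
  set.seed(101)
  X2 <- matrix(rnorm(40), 20, 2)
  y2 <- rep(1:4, each = 5)
  expect_identical(spxy_split(X2, y2), spxy_split(X2, y2))
  expect_error(spxy_split(X2[1:3, ], y2[1:3]), class = "beefhsi_value_error")
})

test_that("SPXY equals a brute-force Kennard-Stone implementation on small n", {
  brute_spxy <- function(X, y, frac) {
    n <- nrow(X)
    dx <- as.matrix(dist(X)); dy <- as.matrix(dist(y))
    d <- dx / max(dx) + dy / max(dy)
    sel <- integer(0)
    best <- which(d == max(d), arr.ind = TRUE)[1, ]
    sel <- sort(unique(as.integer(best)))
    while (length(sel) < ceiling(frac * n)) {
      rest <- setdiff(seq_len(n), sel)
      mind <- vapply(rest, function(i) min(d[i, sel]), 0)
      sel <- c(sel, rest[which.max(mind)])
    }
    sort(sel)
  }
  set.seed(102)
  for (rep in 1:5) {
    X <- matrix(rnorm(12 * 3), 12, 3)
    y <- sample(1:4, 12, replace = TRUE)
    expect_identical(spxy_split(X, y, 0.75)$train_ids, brute_spxy(X, y, 0.75))
  }
})

test_that("stratified folds balance classes and partition the samples", {
  y <- rep(freshness_classes(), each = 10)
  folds <- stratified_kfold(y, k = 10, seed = 5)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(unname(table(y[f$val_ids])), rep(1L, 4), ignore_attr = TRUE)
    expect_identical(sort(c(f$train_ids, f$val_ids)), seq_along(y))
  }
  vals <- sort(unlist(lapply(folds, `[[`, "val_ids")))
  expect_identical(vals, seq_along(y))
  expect_identical(stratified_kfold(y, 10, seed = 5),
                   stratified_kfold(y, 10, seed = 5))
  expect_warning(f2 <- stratified_kfold(rep(c("F", "F-S"), c(20, 3)), 10),
                 "lowered")
  expect_length(f2, 3)
})

test_that("confusion metrics match hand arithmetic on one-vs-rest counts", {
  m <- binary_metrics(tp = 9, tn = 85, fp = 5, fn = 1)
  expect_equal(unname(m["acc"]), 0.940)
  expect_equal(unname(m["sen"]), 0.900)
  expect_equal(unname(m["spec"]), 0.9444, tolerance = 1e-4)
})

test_that("confusion builds the matrix with an unassigned error column", {
  actual <- c("F", "F", "F-S", "F-T-3", "F-T-5", "F-T-5")
  predicted <- c("F", "F-S", "F-S", NA, "F-T-5", "F-T-5")
  rep_ <- confusion(actual, predicted)
  expect_equal(sum(rep_$confusion), 6)
  expect_equal(rep_$acc, 4 / 6)
  expect_equal(rep_$confusion["F-T-3", "unassigned"], 1)
  expect_equal(unname(rep_$sen["F"]), 0.5)
  expect_equal(unname(rep_$sen["F-T-5"]), 1)
  # perfect prediction: identity matrix, all metrics 1
  p <- confusion(actual, actual)
  expect_equal(p$acc, 1)
  expect_true(all(p$sen == 1))
  expect_true(all(p$spec == 1))
  # all one class: that class SEN 1, others 0
  allf <- confusion(actual, rep("F", 6))
  expect_equal(unname(allf$sen["F"]), 1)
  expect_equal(unname(allf$sen["F-S"]), 0)
  expect_error(confusion(actual, c(predicted[-6], "bogus")),
               class = "beefhsi_value_error")
})

test_that("the spectral angle mapper has the textbook geometry", {
  expect_equal(sam_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sam_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(sam_angle(c(1, 0), c(1, 1)), 45)
  x <- c(0.2, 0.5, 0.3); y <- c(0.1, 0.4, 0.6)
  expect_lt(abs(sam_angle(2 * x, y) - sam_angle(x, y)), 1e-10)
  expect_lt(abs(sam_angle(x, 7 * y) - sam_angle(x, y)), 1e-10)
  expect_error(sam_angle(c(0, 0), c(1, 1)), class = "beefhsi_value_error")
})

test_that("class SAM summaries respect degenerate and pairing cases", {
  X <- matrix(rep(c(0.2, 0.4, 0.3), 8), 8, 3, byrow = TRUE)
  ds <- spectral_dataset(X, rep(freshness_classes(), 2),
                         rep("muscle", 8), c(500, 550, 600))
  ang <- class_sam_summary(ds, "muscle")
  expect_equal(unname(ang), rep(0, 3), tolerance = 1e-5)
  expect_length(class_sam_summary(ds, "muscle", pairing = "consecutive"), 3)
  expect_error(class_sam_summary(ds, "fat"), class = "beefhsi_value_error")
})

test_that("run_experiment wires split, selection and models together", {
  scenes <- make_dataset(6, small_config(n_bands = 80L), seed = 71L)
  ex <- extract_spectra(scenes)
  r <- run_experiment(ex, "differentiated", "plsda", cars_runs = 15L,
                      cv_folds = 3L, seed = 7L)
  expect_s3_class(r$report, "evaluation_report")
  expect_s3_class(r$cv_report, "evaluation_report")
  expect_lt(length(r$selection$muscle$selected_indices), 80)
  expect_lt(length(r$selection$fat$selected_indices), 80)
  expect_length(intersect(r$split$train_ids, r$split$test_ids), 0)
  # deterministic end to end
  r2 <- run_experiment(ex, "differentiated", "plsda", cars_runs = 15L,
                       cv_folds = 3L, seed = 7L)
  expect_identical(r$report$confusion, r2$report$confusion)
  expect_identical(r$selection$muscle$selected_indices,
                   r2$selection$muscle$selected_indices)
  # overall-average mode runs with one model on the cut spectra
  ro <- run_experiment(ex, "overall_average", "plsda", cars_runs = 15L,
                       cv_folds = 3L, seed = 7L)
  expect_named(ro$models, "cut")
})
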