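make_sep_dataset <- function(n_per_class = 8, p = 20, gap = 3, seed = 55) {
  set.seed(seed)
  y <- rep(freshness_classes(), each = n_per_class)
  codes <- rep(1:4, each = n_per_class)
  X <- matrix(rnorm(length(y) * p, sd = 0.3), length(y), p)
  X[, 1] <- X[, 1] + gap * codes
  X[, 2] <- X[, 2] - gap * codes
  list(X = X, y = y)
}

test_that("PLS-DA separates well-spaced classes and is deterministic", {
  d <- make_sep_dataset()
  m1 <- fit_plsda(d$X, d$y)
  m2 <- fit_plsda(d$X, d$y)
  expect_identical(m1$pls$coef, m2$pls$coef)
  expect_equal(predict_class(m1, d$X), d$y)
  expect_error(fit_plsda(d$X[1:8, ], d$y[1:8]), class = "beefhsi_value_error")
  # component cap keeps tiny problems valid
  tiny <- fit_plsda(d$X[c(1, 9, 17, 25), ], d$y[c(1, 9, 17, 25)])
  expect_lte(tiny$pls$n_components, 3)
})

test_that("the +/-0.5 assignment rule rejects out-of-band and boundary scores", {
  d <- make_sep_dataset()
  m <- fit_plsda(d$X, d$y)
  fake <- m
  # exercise the rule directly through crafted scores
  scores <- c(2.4, 4.7, 2.5, 0.2, 1.0)
  k <- round(scores)
  ok <- k >= 1 & k <= 4 & abs(scores - k) < 0.5
  expect_equal(ok, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # and end to end: a score far outside the scale comes back unassigned
  far <- d$X[1, , drop = FALSE]
  far[1] <- far[1] + 1000
  expect_true(is.na(assign_plsda(m, far)$label))
})

test_that("noiseless endmember training gives exact ordinal scores", {
  lib <- make_endmembers()
  X <- do.call(rbind, lib$muscle_by_class)
  y <- freshness_classes()
  m <- fit_plsda(X, y)
  sc <- assign_plsda(m, X)$score
  expect_equal(sc, 1:4, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("one-vs-rest RBF SVM classifies separated clusters", {
  set.seed(56)
  A <- cbind(rnorm(30), rnorm(30))
  B <- cbind(rnorm(30) + 6, rnorm(30))
  X <- rbind(A, B)
  y <- rep(c("F", "F-T-5"), each = 30)
  m <- fit_svm(X, y, C = 1, gamma = 1)
  expect_equal(predict_class(m, X), y)
  # duplicating a training sample does not change predictions
  m2 <- fit_svm(rbind(X, X[1, ]), c(y, y[1]), C = 1, gamma = 1)
  probe <- rbind(c(0, 0), c(6, 0), c(3, 1))
  expect_equal(predict_class(m, probe), predict_class(m2, probe))
  expect_error(fit_svm(A, rep("F", 30)), class = "beefhsi_value_error")
})

test_that("SVM predictions are invariant to band reordering", {
  d <- make_sep_dataset()
  m1 <- fit_svm(d$X, d$y, C = 10, gamma = 0.05)
  perm <- sample(ncol(d$X))
  m2 <- fit_svm(d$X[, perm], d$y, C = 10, gamma = 0.05)
  expect_equal(predict_class(m1, d$X), predict_class(m2, d$X[, perm]))
})

test_that("tune_svm searches the grid deterministically", {
  d <- make_sep_dataset(n_per_class = 10)
  t1 <- tune_svm(d$X, d$y, C_grid = c(0.18, 10), gamma_grid = c(0.008, 0.1),
                 seed = 3)
  t2 <- tune_svm(d$X, d$y, C_grid = c(0.18, 10), gamma_grid = c(0.008, 0.1),
                 seed = 3)
  expect_identical(t1, t2)
  expect_gte(t1$cv_acc, 0.5)
})

test_that("the BP network learns XOR for most seeds and is reproducible", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("F", "F-S", "F-S", "F")
  X10 <- X[rep(1:4, 3), ] + matrix(rnorm(24, sd = 0.01), 12, 2)
  y10 <- rep(y, 3)
  wins <- vapply(1:10, function(s) {
    m <- fit_ann(X10, y10, hidden_nodes = 4, epochs = 2000, lr = 0.05,
                 seed = s)
    mean(predict_class(m, X10) == y10) == 1
  }, TRUE)
  expect_gte(sum(wins), 8)
  m1 <- fit_ann(X10, y10, hidden_nodes = 4, epochs = 50, seed = 9)
  m2 <- fit_ann(X10, y10, hidden_nodes = 4, epochs = 50, seed = 9)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_equal(nrow(m1$W2), 4L)  # output width is always the 4 classes
})

test_that("predict_class enforces the uniform prediction contract", {
  d <- make_sep_dataset()
  for (kind in c("plsda", "svm", "ann")) {
    m <- fit_classifier(kind, d$X, d$y)
    expect_identical(predict_class(m, d$X[0, , drop = FALSE]), character(0))
    expect_error(predict_class(m, d$X[, 1:3]), "3",
                 class = "beefhsi_shape_error")
    expect_identical(predict_class(m, d$X), predict_class(m, d$X))
  }
})

test_that("tissue predictions combine by area with muscle as the anchor", {
  mus <- c("F", "F", "F-S", NA, "F")
  fat <- c("F-T-3", NA, "F-T-3", "F-S", "F-T-5")
  ff <- c(0.2, 0.4, 0.7, 0.3, 0.6)
  out <- combine_tissue_predictions(mus, fat, ff)
  expect_equal(out, c("F", "F", "F-T-3", "F-S", "F-T-5"))
  out2 <- combine_tissue_predictions(mus, fat, ff,
                                     strategy = "muscle_priority")
  expect_equal(out2, c("F", "F", "F-T-3", NA, "F-T-5"))
})
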