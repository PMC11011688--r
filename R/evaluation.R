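#' SPXY train/test partitioning
#'
#' Sample-set partitioning based on joint x-y distances: pairwise Euclidean
#' distances are computed separately in predictor space and response space,
#' each normalized by its maximum, and summed; Kennard-Stone selection on
#' the combined distance picks the training set (seeded with the pair at
#' maximal distance, then repeatedly adding the sample whose minimum
#' distance to the selected set is largest) until
#' `ceiling(train_fraction * n)` samples are selected. Deterministic.
#'
#' @param X predictor matrix.
#' @param y_codes numeric response codes (the ordinal class codes 1-4 here);
#'   a 0/1 class-mismatch distance is used instead when
#'   `y_distance = "mismatch"`.
#' @param train_fraction training share (default 0.75).
#' @param y_distance `"euclidean"` (ordinal codes) or `"mismatch"`.
#' @return list with integer `train_ids`, `test_ids`.
#' @export
spxy_split <- function(X, y_codes, train_fraction = 0.75,
                       y_distance = c("euclidean", "mismatch")) {
  y_distance <- match.arg(y_distance)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) {
    stop_beefhsi("spxy_split needs n >= 4", class = "beefhsi_value_error")
  }
  dx <- as.matrix(stats::dist(X))
  dy <- if (y_distance == "euclidean") {
    as.matrix(stats::dist(as.numeric(y_codes)))
  } else {
    outer(y_codes, y_codes, FUN = function(a, b) as.numeric(a != b))
  }
  mx <- max(dx); my <- max(dy)
  if (mx == 0) { warning("zero spread in X; x-term dropped from SPXY"); mx <- 1; dx[] <- 0 }
  if (my == 0) { warning("zero spread in y; y-term dropped from SPXY"); my <- 1; dy[] <- 0 }
  d <- dx / mx + dy / my
  n_train <- ceiling(train_fraction * n)
  start <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel <- sort(unique(as.integer(start)))
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_train) {
    mind[sel] <- -Inf
    nxt <- unname(which.max(mind))  # first index on ties: deterministic
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  train <- sort(sel)
  list(train_ids = train, test_ids = setdiff(seq_len(n), train))
}

#' Stratified k-fold partition
#'
#' Splits sample ids into `k` folds so per-class counts across folds differ
#' by at most one; every sample validates exactly once. If some class has
#' fewer than `k` members, `k` is lowered to the minimum class count with a
#' warning.
#'
#' @param y class labels.
#' @param k fold count (default 10).
#' @param seed shuffle seed.
#' @return list of `k` lists with `train_ids`, `val_ids`.
#' @export
stratified_kfold <- function(y, k = 10L, seed = 1L) {
  tab <- table(y)
  if (any(tab == 0L)) stop_beefhsi("empty class", class = "beefhsi_value_error")
  if (min(tab) < k) {
    k <- as.integer(min(tab))
    warning(sprintf("k lowered to %d (minimum class count)", k))
  }
  if (k < 2L) {
    stop_beefhsi("stratified_kfold needs k >= 2 after adjustment",
                 class = "beefhsi_value_error")
  }
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cls in names(tab)) {
      ids <- sample(which(y == cls))
      fold_of[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train_ids = which(fold_of != f), val_ids = which(fold_of == f))
  })
}

#' Confusion matrix and ACC/SEN/SPEC metrics
#'
#' Builds the actual x predicted count matrix over the four freshness
#' classes, with a dedicated `unassigned` column for rejected (NA)
#' predictions, which count as errors. Overall ACC is the plain fraction of
#' correct labels; per-class sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` follow the one-vs-rest reading of the confusion matrix.
#'
#' @param actual,predicted character label vectors of equal length
#'   (`predicted` may contain `NA` = unassigned).
#' @return An `evaluation_report`: `confusion` (4 x 5 matrix), `acc`,
#'   `sen` and `spec` (named per-class vectors), `n`.
#' @export
confusion <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  classes <- freshness_classes()
  class_code(actual)
  if (!all(predicted %in% c(classes, NA))) {
    stop_beefhsi("unknown predicted label", class = "beefhsi_value_error")
  }
  pred <- ifelse(is.na(predicted), "unassigned", predicted)
  cm <- table(factor(actual, levels = classes),
              factor(pred, levels = c(classes, "unassigned")))
  cm <- unclass(cm)
  n <- length(actual)
  acc <- sum(diag(cm[, classes])) / n
  sen <- spec <- stats::setNames(numeric(4), classes)
  for (k in classes) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    sen[k] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[k] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  structure(list(confusion = cm, acc = acc, sen = sen, spec = spec, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, ACC = %.4f\n", x$n, x$acc))
  print(x$confusion)
  invisible(x)
}

#' Binary classification metrics from raw counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`.
#'
#' @param tp,tn,fp,fn nonnegative counts.
#' @return named numeric vector `c(acc, sen, spec)`.
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  c(acc = (tp + tn) / (tp + tn + fp + fn),
    sen = tp / (tp + fn),
    spec = tn / (tn + fp))
}

#' Spectral angle mapper
#'
#' The angle between two spectra treated as vectors:
#' `acos(<x, y> / (|x| |y|))` in degrees, clipped to [0, 180]. Invariant to
#' positive scaling of either spectrum.
#'
#' @param x,y nonzero numeric vectors of equal length.
#' @return angle in degrees.
#' @export
sam_angle <- function(x, y) {
  assert_spectrum_pair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop_beefhsi("sam_angle: zero vector", class = "beefhsi_value_error")
  }
  cth <- sum(x * y) / (nx * ny)
  acos(min(1, max(-1, cth))) * 180 / pi
}

#' Spectral-angle summary of class differences
#'
#' For the chosen tissue, the SAM angle between the fresh-class mean
#' spectrum and the mean spectrum of each processed class
#' (`pairing = "f_vs_each"`, default), or between consecutive classes
#' (`pairing = "consecutive"`).
#'
#' @param dataset a [spectral_dataset].
#' @param tissue `"muscle"`, `"fat"` or `"cut"`.
#' @param pairing see Description.
#' @return named numeric vector of three angles (degrees).
#' @export
class_sam_summary <- function(dataset, tissue = "muscle",
                              pairing = c("f_vs_each", "consecutive")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(dataset, "spectral_dataset"))
  rows <- dataset$tissue == tissue
  if (!any(rows)) {
    stop_beefhsi("no rows for tissue '%s'", tissue,
                 class = "beefhsi_value_error")
  }
  classes <- freshness_classes()
  means <- lapply(classes, function(cl) {
    r <- rows & dataset$y == cl
    if (!any(r)) {
      stop_beefhsi("class '%s' missing for tissue '%s'", cl, tissue,
                   class = "beefhsi_value_error")
    }
    colMeans(dataset$X[r, , drop = FALSE])
  })
  names(means) <- classes
  if (pairing == "f_vs_each") {
    angles <- vapply(classes[-1], function(cl) sam_angle(means[["F"]], means[[cl]]),
                     0)
  } else {
    angles <- vapply(seq_len(3), function(i)
      sam_angle(means[[classes[i]]], means[[classes[i + 1]]]), 0)
    names(angles) <- paste(classes[-4], classes[-1], sep = " vs ")
  }
  angles
}

#' Run one classification experiment design
#'
#' The full modeling protocol on extracted spectra: SPXY split at the
#' sample (scene) level, optional CARS wavelength selection on the training
#' rows only, classifier fit on training, evaluation on the held-out
#' prediction set, plus a stratified cross-validation report on the
#' training set. In `tissue_mode = "differentiated"` the muscle and fat
#' rows get independent CARS selections and classifiers whose predictions
#' are combined per sample by [combine_tissue_predictions()];
#' `"overall_average"` uses one classifier on the whole-cut mean spectra.
#'
#' @param extracted the result of [extract_spectra()].
#' @param tissue_mode `"differentiated"` or `"overall_average"`.
#' @param classifier `"plsda"`, `"svm"` or `"ann"`.
#' @param use_cars apply CARS wavelength selection (default TRUE).
#' @param train_fraction SPXY training share (default 0.75).
#' @param cv_folds stratified CV folds on the training set (default 10,
#'   lowered automatically for small classes).
#' @param cars_runs CARS sampling runs (default 50).
#' @param seed master seed for CARS, CV and the ANN initialization.
#' @param classifier_args extra arguments for the classifier fitter.
#' @param svm_tune select `(C, gamma)` by stratified CV on the training
#'   rows via [tune_svm()] (default TRUE, the study's protocol); with
#'   FALSE, [fit_svm()]'s defaults (or `classifier_args`) are used as-is.
#' @param strategy tissue-combination strategy (differentiated mode).
#' @return list with `report` (held-out [confusion()] report), `cv_report`,
#'   `selection` (CARS results or NULL), `split`, `models`.
#' @export
run_experiment <- function(extracted,
                           tissue_mode = c("differentiated", "overall_average"),
                           classifier = c("plsda", "svm", "ann"),
                           use_cars = TRUE, train_fraction = 0.75,
                           cv_folds = 10L, cars_runs = 50L, seed = 1L,
                           classifier_args = list(), svm_tune = TRUE,
                           strategy = "area_weighted_vote") {
  tissue_mode <- match.arg(tissue_mode)
  classifier <- match.arg(classifier)
  seeds <- derive_seeds(seed, 4L)
  cut_ds <- extracted$cut
  n <- nrow(cut_ds$X)
  split <- spxy_split(cut_ds$X, class_code(cut_ds$y), train_fraction)
  fit_one <- function(X, y, seed_k) {
    args <- c(list(kind = classifier, X = X, y = y), classifier_args)
    if (classifier == "ann" && is.null(classifier_args$seed)) {
      args$seed <- seed_k
    }
    if (classifier == "svm" && svm_tune &&
        is.null(classifier_args$C) && is.null(classifier_args$gamma)) {
      tuned <- tune_svm(X, y, seed = seed_k)
      args$C <- tuned$C
      args$gamma <- tuned$gamma
    }
    do.call(fit_classifier, args)
  }
  if (tissue_mode == "overall_average") {
    tr <- split$train_ids; te <- split$test_ids
    Xtr <- cut_ds$X[tr, , drop = FALSE]; ytr <- cut_ds$y[tr]
    sel <- NULL
    cols <- seq_len(ncol(Xtr))
    if (use_cars) {
      sel <- cars_select(Xtr, class_code(ytr), total_runs = cars_runs,
                         n_folds = max(2L, min(10L, nrow(Xtr) %/% 2L)),
                         seed = seeds[1])
      cols <- sel$selected_indices
    }
    model <- fit_one(Xtr[, cols, drop = FALSE], ytr, seeds[2])
    pred <- predict_class(model, cut_ds$X[te, cols, drop = FALSE])
    report <- confusion(cut_ds$y[te], pred)
    cv_report <- cv_evaluate(Xtr[, cols, drop = FALSE], ytr, fit_one,
                             cv_folds, seeds[3])
    models <- list(cut = model)
    selection <- if (use_cars) list(cut = sel) else NULL
  } else {
    ts <- extracted$tissue
    # sample-level split by scene id so the two tissue rows of a scene
    # never straddle the train/test boundary (leakage guard)
    tr_samples <- extracted$cut$sample_id[split$train_ids]
    te_samples <- extracted$cut$sample_id[split$test_ids]
    selection <- list(); models <- list()
    preds <- list()
    for (k in c("muscle", "fat")) {
      rows_tr <- which(ts$tissue == k & ts$sample_id %in% tr_samples)
      Xtr <- ts$X[rows_tr, , drop = FALSE]; ytr <- ts$y[rows_tr]
      cols <- seq_len(ncol(Xtr))
      if (use_cars) {
        sel <- cars_select(Xtr, class_code(ytr), total_runs = cars_runs,
                           n_folds = max(2L, min(10L, nrow(Xtr) %/% 2L)),
                           seed = seeds[1] + match(k, c("muscle", "fat")))
        selection[[k]] <- sel
        cols <- sel$selected_indices
      }
      models[[k]] <- fit_one(Xtr[, cols, drop = FALSE], ytr, seeds[2])
      rows_all <- which(ts$tissue == k)
      p <- predict_class(models[[k]], ts$X[rows_all, cols, drop = FALSE])
      preds[[k]] <- stats::setNames(p, ts$sample_id[rows_all])
    }
    area <- extracted$area
    comb <- function(samples) {
      ml <- preds$muscle[as.character(samples)]
      fl <- preds$fat[as.character(samples)]
      ff <- area$fat_fraction[match(samples, area$sample_id)]
      combine_tissue_predictions(unname(ml), unname(fl), ff,
                                 strategy = strategy)
    }
    report <- confusion(cut_ds$y[split$test_ids], comb(te_samples))
    # CV on training samples: refit per fold on muscle rows (the dominant
    # tissue) is expensive; the CV report instead evaluates the combined
    # training-sample predictions fold-wise with refit per fold
    cv_report <- cv_evaluate_differentiated(extracted, tr_samples, fit_one,
                                            selection, use_cars, cv_folds,
                                            seeds[3], strategy)
    if (!use_cars) selection <- NULL
  }
  list(report = report, cv_report = cv_report, selection = selection,
       split = split, models = models)
}

cv_evaluate <- function(X, y, fit_one, cv_folds, seed) {
  folds <- suppressWarnings(stratified_kfold(y, cv_folds, seed))
  actual <- character(0); predicted <- character(0)
  for (f in folds) {
    m <- fit_one(X[f$train_ids, , drop = FALSE], y[f$train_ids], seed)
    actual <- c(actual, y[f$val_ids])
    predicted <- c(predicted, predict_class(m, X[f$val_ids, , drop = FALSE]))
  }
  confusion(actual, predicted)
}

cv_evaluate_differentiated <- function(extracted, tr_samples, fit_one,
                                       selection, use_cars, cv_folds, seed,
                                       strategy) {
  ts <- extracted$tissue
  cut_ds <- extracted$cut
  area <- extracted$area
  tr_idx <- match(tr_samples, cut_ds$sample_id)
  y_tr <- cut_ds$y[tr_idx]
  folds <- suppressWarnings(stratified_kfold(y_tr, cv_folds, seed))
  actual <- character(0); predicted <- character(0)
  for (f in folds) {
    fit_samples <- tr_samples[f$train_ids]
    val_samples <- tr_samples[f$val_ids]
    preds <- list()
    for (k in c("muscle", "fat")) {
      cols <- if (use_cars) selection[[k]]$selected_indices
              else seq_len(ncol(ts$X))
      rows_fit <- which(ts$tissue == k & ts$sample_id %in% fit_samples)
      m <- fit_one(ts$X[rows_fit, cols, drop = FALSE], ts$y[rows_fit], seed)
      rows_val <- which(ts$tissue == k & ts$sample_id %in% val_samples)
      p <- predict_class(m, ts$X[rows_val, cols, drop = FALSE])
      preds[[k]] <- stats::setNames(p, ts$sample_id[rows_val])
    }
    ml <- preds$muscle[as.character(val_samples)]
    fl <- preds$fat[as.character(val_samples)]
    ff <- area$fat_fraction[match(val_samples, area$sample_id)]
    actual <- c(actual, y_tr[f$val_ids])
    predicted <- c(predicted,
                   combine_tissue_predictions(unname(ml), unname(fl), ff,
                                              strategy = strategy))
  }
  confusion(actual, predicted)
}
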