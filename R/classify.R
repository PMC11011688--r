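#' PLS-DA with ordinal class coding
#'
#' Regresses the spectra on the ordinal class codes 1-4 (F, F-S, F-T-3,
#' F-T-5) with the PLS1 engine. Class assignment applies the +/-0.5 rule:
#' a sample with continuous score `s` is assigned class `k` iff
#' `|s - k| < 0.5`; scores outside (0.5, 4.5), and exact half-integer
#' boundaries, are unassigned (`NA`), which every accuracy metric counts as
#' an error.
#'
#' @param X training spectra matrix.
#' @param y training class labels ([freshness_classes()]).
#' @param n_components latent variables (default 10, capped at rank limits).
#' @return A `plsda_model`.
#' @export
fit_plsda <- function(X, y, n_components = 10L) {
  X <- as.matrix(X)
  codes <- class_code(y)
  if (length(unique(codes)) < 2L) {
    stop_beefhsi("fit_plsda needs >= 2 classes in training data",
                 class = "beefhsi_value_error")
  }
  m <- fit_pls(X, codes, n_components)
  structure(list(pls = m, threshold = 0.5, n_features = ncol(X)),
            class = "plsda_model")
}

#' @rdname fit_plsda
#' @param model a `plsda_model`.
#' @param newdata spectra matrix with the training column count.
#' @return `assign_plsda`: list with `label` (character, `NA` =
#'   unassigned) and `score` (continuous deterioration-scale value).
#' @export
assign_plsda <- function(model, newdata) {
  score <- predict_pls(model$pls, newdata)
  k <- round(score)
  ok <- k >= 1 & k <= 4 & abs(score - k) < model$threshold
  label <- ifelse(ok, freshness_classes()[pmin.int(pmax.int(k, 1), 4)],
                  NA_character_)
  list(label = label, score = score)
}

#' One-vs-rest radial-basis SVM
#'
#' Four binary soft-margin RBF machines, one per class (the one-hot output
#' coding), each trained class-vs-rest; prediction is the argmax of the
#' four decision values, ties broken toward the lower (fresher) class
#' index. Inputs are standardized by the training mean/sd. The default
#' hyperparameters are the study's cross-validated `(C, gamma) =
#' (0.18, 0.008)`.
#'
#' @param X training spectra matrix.
#' @param y training class labels.
#' @param C soft-margin penalty (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return An `svm_ovr_model`.
#' @export
fit_svm <- function(X, y, C = 0.18, gamma = 0.008) {
  stopifnot(C > 0, gamma > 0)
  X <- as.matrix(X)
  codes <- class_code(y)
  if (length(unique(codes)) < 2L) {
    stop_beefhsi("fit_svm needs >= 2 classes", class = "beefhsi_value_error")
  }
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  machines <- lapply(1:4, function(k) {
    yk <- factor(ifelse(codes == k, "pos", "neg"), levels = c("pos", "neg"))
    if (length(unique(yk)) < 2L) return(NULL)  # class absent from training
    e1071::svm(Xs, yk, kernel = "radial", cost = C, gamma = gamma,
               scale = FALSE)
  })
  structure(list(machines = machines, x_mean = mu, x_sd = sd_,
                 C = C, gamma = gamma, n_features = ncol(X)),
            class = "svm_ovr_model")
}

#' Cross-validated (C, gamma) selection for the RBF SVM
#'
#' Grid search over the soft-margin penalty and kernel width by stratified
#' k-fold accuracy, mirroring the protocol that produced the study's
#' reported `(C, gamma) = (0.18, 0.008)` on its own data. Ties go to the
#' first grid point (grid order is deterministic).
#'
#' @param X training spectra matrix.
#' @param y training class labels.
#' @param C_grid,gamma_grid candidate values.
#' @param n_folds stratified CV folds (default 5).
#' @param seed fold seed.
#' @return list with `C`, `gamma`, `cv_acc`.
#' @export
tune_svm <- function(X, y, C_grid = c(0.18, 1, 10, 100),
                     gamma_grid = c(0.008, 0.02, 0.1, 0.5),
                     n_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  folds <- suppressWarnings(stratified_kfold(y, n_folds, seed))
  best <- list(C = C_grid[1], gamma = gamma_grid[1], cv_acc = -1)
  for (C in C_grid) for (g in gamma_grid) {
    ok <- unlist(lapply(folds, function(f) {
      m <- fit_svm(X[f$train_ids, , drop = FALSE], y[f$train_ids],
                   C = C, gamma = g)
      predict_class(m, X[f$val_ids, , drop = FALSE]) == y[f$val_ids]
    }))
    acc <- mean(ok)
    if (acc > best$cv_acc) best <- list(C = C, gamma = g, cv_acc = acc)
  }
  best
}

svm_decision_values <- function(model, newdata) {
  newdata <- rbind(newdata)
  Xs <- sweep(sweep(newdata, 2, model$x_mean), 2, model$x_sd, "/")
  vapply(model$machines, function(m) {
    if (is.null(m)) return(rep(-Inf, nrow(Xs)))
    dv <- attr(stats::predict(m, Xs, decision.values = TRUE),
               "decision.values")
    # orient so positive favors the "pos" (class) side
    if (colnames(dv)[1] == "pos/neg") drop(dv) else -drop(dv)
  }, numeric(nrow(Xs)))
}

#' Back-propagation neural network classifier
#'
#' A three-layer feed-forward network: hyperbolic-tangent-sigmoid hidden
#' layer, linear output layer of width 4 (one-hot class targets), trained
#' by seeded full-batch gradient descent with momentum on the
#' sum-of-squares loss. Inputs are standardized by the training mean/sd.
#' Prediction is the argmax of the four outputs.
#'
#' @param X training spectra matrix.
#' @param y training class labels.
#' @param hidden_nodes hidden-layer width (default 10).
#' @param epochs training epochs (default 2000).
#' @param lr learning rate (default 0.05).
#' @param momentum momentum coefficient (default 0.9).
#' @param decay L2 weight-decay coefficient on the connection weights
#'   (default 0.005); regularizes away uninformative standardized inputs.
#' @param seed weight-initialization seed.
#' @return An `ann_model`.
#' @export
fit_ann <- function(X, y, hidden_nodes = 10L, epochs = 2000L, lr = 0.05,
                    momentum = 0.9, decay = 0.005, seed = 1L) {
  stopifnot(hidden_nodes >= 1L, epochs >= 1L, lr > 0)
  X <- as.matrix(X)
  codes <- class_code(y)
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  Tm <- matrix(0, n, 4)
  Tm[cbind(seq_len(n), codes)] <- 1
  with_seed(seed, {
    W1 <- matrix(stats::runif(hidden_nodes * d, -0.5, 0.5), hidden_nodes, d) /
      sqrt(d)
    b1 <- numeric(hidden_nodes)
    W2 <- matrix(stats::runif(4L * hidden_nodes, -0.5, 0.5), 4L, hidden_nodes) /
      sqrt(hidden_nodes)
    b2 <- numeric(4L)
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
    for (ep in seq_len(epochs)) {
      H <- tanh(Xs %*% t(W1) + matrix(b1, n, hidden_nodes, byrow = TRUE))
      O <- H %*% t(W2) + matrix(b2, n, 4L, byrow = TRUE)
      err <- O - Tm                                   # n x 4
      if (!all(is.finite(err))) {
        stop_beefhsi("ANN training diverged at epoch %d (non-finite loss)",
                     ep, class = "beefhsi_numeric_error")
      }
      gW2 <- crossprod(err, H) / n + decay * W2       # 4 x h
      gb2 <- colMeans(err)
      dH <- (err %*% W2) * (1 - H^2)                  # n x h
      gW1 <- crossprod(dH, Xs) / n + decay * W1       # h x d
      gb1 <- colMeans(dH)
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   x_mean = mu, x_sd = sd_, hidden_nodes = hidden_nodes,
                   epochs = epochs, lr = lr, momentum = momentum,
                   decay = decay, seed = seed, n_features = d),
              class = "ann_model")
  })
}

ann_outputs <- function(model, newdata) {
  newdata <- rbind(newdata)
  Xs <- sweep(sweep(newdata, 2, model$x_mean), 2, model$x_sd, "/")
  H <- tanh(Xs %*% t(model$W1) +
              matrix(model$b1, nrow(Xs), model$hidden_nodes, byrow = TRUE))
  H %*% t(model$W2) + matrix(model$b2, nrow(Xs), 4L, byrow = TRUE)
}

#' Predict class labels from any of the three classifier models
#'
#' Uniform prediction contract: one label per row (PLS-DA may return `NA`
#' for unassigned samples). Deterministic for all model kinds.
#'
#' @param model a `plsda_model`, `svm_ovr_model` or `ann_model`.
#' @param newdata spectra matrix with the training column count.
#' @return character vector of class labels.
#' @export
predict_class <- function(model, newdata) {
  newdata <- rbind(newdata)
  if (nrow(newdata) == 0L) return(character(0))
  if (ncol(newdata) != model$n_features) {
    stop_beefhsi("expected %d feature columns, got %d", model$n_features,
                 ncol(newdata), class = "beefhsi_shape_error")
  }
  if (inherits(model, "plsda_model")) {
    assign_plsda(model, newdata)$label
  } else if (inherits(model, "svm_ovr_model")) {
    dv <- rbind(svm_decision_values(model, newdata))
    freshness_classes()[apply(dv, 1, which.max)]
  } else if (inherits(model, "ann_model")) {
    O <- ann_outputs(model, newdata)
    freshness_classes()[apply(O, 1, which.max)]
  } else {
    stop_beefhsi("unknown model class", class = "beefhsi_value_error")
  }
}

#' Fit a classifier by name
#'
#' @param kind one of `"plsda"`, `"svm"`, `"ann"`.
#' @param X,y training data.
#' @param ... passed to the specific fitter.
#' @return the fitted model.
#' @export
fit_classifier <- function(kind = c("plsda", "svm", "ann"), X, y, ...) {
  kind <- match.arg(kind)
  switch(kind,
         plsda = fit_plsda(X, y, ...),
         svm = fit_svm(X, y, ...),
         ann = fit_ann(X, y, ...))
}

#' Differentiated-tissue classification of whole samples
#'
#' Tissue-specific classifiers (trained on tissue-specific wavelength
#' subsets) each predict per sample; the per-sample label combines them by
#' one of two strategies. `"area_weighted_vote"` (default): muscle and fat
#' predictions vote with weights equal to their areal fractions, ties to
#' the muscle prediction. `"muscle_priority"`: the muscle prediction wins
#' unless the fat areal fraction exceeds 0.5, in which case fat wins.
#' Samples without fat pixels always take the muscle prediction.
#'
#' @param muscle_label,fat_label character predictions (fat may be `NA`
#'   where absent).
#' @param fat_fraction numeric areal fat fraction per sample.
#' @param strategy combination rule.
#' @return character vector of combined labels.
#' @export
combine_tissue_predictions <- function(muscle_label, fat_label, fat_fraction,
                                       strategy = c("area_weighted_vote",
                                                    "muscle_priority")) {
  strategy <- match.arg(strategy)
  n <- length(muscle_label)
  stopifnot(length(fat_label) == n, length(fat_fraction) == n)
  out <- muscle_label
  have_fat <- !is.na(fat_label)
  if (strategy == "muscle_priority") {
    take_fat <- have_fat & fat_fraction > 0.5
    out[take_fat] <- fat_label[take_fat]
  } else {
    # two voters: weight (1 - fat_fraction) for muscle, fat_fraction for fat;
    # fat wins only with the strictly larger area
    take_fat <- have_fat & fat_fraction > 0.5 &
      (is.na(muscle_label) | fat_label != muscle_label)
    out[take_fat] <- fat_label[take_fat]
    # an unassigned muscle vote defers to any assigned fat vote
    defer <- is.na(muscle_label) & have_fat
    out[defer] <- fat_label[defer]
  }
  out
}
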