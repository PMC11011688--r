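#' Partial least squares regression (PLS1, NIPALS)
#'
#' Univariate-response PLS fitted by NIPALS: components are extracted to
#' maximize covariance between the predictors and the response. Predictors
#' and response are mean-centered; no variance scaling is applied (all
#' bands share reflectance units). Zero-variance predictor columns carry no
#' covariance and simply receive zero weights.
#'
#' With `n_components` equal to the column rank of the centered predictor
#' matrix, the coefficient vector equals the least-squares solution.
#'
#' @param X predictor matrix (n x p), no missing values.
#' @param y numeric response vector, length n.
#' @param n_components latent-variable count, `<= min(n - 1, p)`.
#' @return A `pls_model`: `coef` (length p), `intercept`, `x_mean`,
#'   `y_mean`, `n_components`.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2L, p >= 1L)
  if (anyNA(X) || anyNA(y)) {
    stop_beefhsi("fit_pls: missing values in X or y",
                 class = "beefhsi_value_error")
  }
  n_components <- min(n_components, n - 1L, p)
  if (n_components < 1L) {
    stop_beefhsi("fit_pls: n_components must be >= 1",
                 class = "beefhsi_value_error")
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  Wm <- matrix(0, p, n_components)
  Pm <- matrix(0, p, n_components)
  qv <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)                 # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break                # no covariance left
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-14) break
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    Wm[, a] <- w; Pm[, a] <- p_; qv[a] <- q_
    a_used <- a
  }
  if (a_used == 0L) {
    coef <- numeric(p)
  } else {
    Wa <- Wm[, seq_len(a_used), drop = FALSE]
    Pa <- Pm[, seq_len(a_used), drop = FALSE]
    qa <- qv[seq_len(a_used)]
    coef <- drop(Wa %*% solve(crossprod(Pa, Wa), qa))
  }
  structure(list(coef = coef, intercept = y_mean - sum(x_mean * coef),
                 x_mean = x_mean, y_mean = y_mean,
                 n_components = a_used),
            class = "pls_model")
}

#' @rdname fit_pls
#' @param model a `pls_model`.
#' @param newdata matrix with the training column count.
#' @return `predict_pls`: numeric vector of predictions.
#' @export
predict_pls <- function(model, newdata) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(model$coef)) {
    stop_beefhsi("predict_pls: expected %d columns, got %d",
                 length(model$coef), ncol(newdata),
                 class = "beefhsi_shape_error")
  }
  drop(newdata %*% model$coef) + model$intercept
}

# Deterministic fold assignment: shuffle indices under the seed, deal
# round-robin into k folds.
cv_folds <- function(n, k, seed) {
  idx <- with_seed(seed, sample.int(n))
  split(idx, rep_len(seq_len(k), n))
}

#' Cross-validated root mean square error of a PLS model
#'
#' k-fold CV with folds formed deterministically from the seed; returns
#' `sqrt(mean((y - yhat_cv)^2))` over all held-out samples.
#'
#' @inheritParams fit_pls
#' @param n_folds fold count, `2 <= n_folds <= n`.
#' @param seed fold-assignment seed.
#' @return nonnegative scalar.
#' @export
rmsecv <- function(X, y, n_components, n_folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_folds < 2L || n_folds > n) {
    stop_beefhsi("rmsecv: need 2 <= n_folds <= n", class = "beefhsi_value_error")
  }
  folds <- cv_folds(n, n_folds, seed)
  pred <- numeric(n)
  for (fold in folds) {
    train <- setdiff(seq_len(n), fold)
    m <- fit_pls(X[train, , drop = FALSE], y[train],
                 min(n_components, length(train) - 1L, ncol(X)))
    pred[fold] <- predict_pls(m, X[fold, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}
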