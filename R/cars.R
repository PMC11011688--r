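#' Exponentially decreasing retention schedule (EDF)
#'
#' The fraction of wavelengths retained at a given sampling run:
#' `r(run) = a * exp(-k * run)` with the constants fixed by the boundary
#' conditions `r(1) = 1` (all variables survive the first run) and
#' `r(total_runs) = 2 / n_predictors` (only two variables survive the
#' last).
#'
#' @param run sampling run index, `1 <= run <= total_runs`.
#' @param total_runs total number of sampling runs.
#' @param n_predictors full wavelength count.
#' @return retention fraction in (0, 1].
#' @export
edf_ratio <- function(run, total_runs, n_predictors) {
  if (n_predictors < 2L) {
    stop_beefhsi("edf_ratio needs n_predictors >= 2",
                 class = "beefhsi_value_error")
  }
  stopifnot(all(run >= 1), all(run <= total_runs))
  if (total_runs == 1L) return(rep(1, length(run)))
  k <- log(n_predictors / 2) / (total_runs - 1)
  a <- exp(k)
  a * exp(-k * run)
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Iteratively shrinks the wavelength set over `total_runs` sampling runs.
#' Each run: (1) fit PLS on a Monte-Carlo subset (`mc_fraction` of the
#' samples) restricted to the currently retained wavelengths; (2) compute
#' normalized weights `w_i = |b_i| / sum |b_j|` from the regression
#' coefficients; (3) enforce the EDF retention count by keeping the
#' top-weighted wavelengths (ties broken toward the lower band index);
#' (4) adaptive reweighted sampling — draw that many wavelengths with
#' replacement with probability `w`, retaining the distinct drawn set;
#' (5) record the 10-fold RMSECV of the retained set on the full sample
#' set. The retained set with minimal RMSECV across runs is selected.
#'
#' @param X predictor matrix (samples x wavelengths).
#' @param y numeric response (here the ordinal class codes 1-4).
#' @param total_runs number of sampling runs (default 50).
#' @param n_folds CV folds for RMSECV (default 10).
#' @param max_components PLS latent-variable cap (default 10; further
#'   capped by retained-variable count and sample count).
#' @param mc_fraction Monte-Carlo sample fraction per run (default 0.8).
#' @param seed integer; fixes every random draw.
#' @return A `cars_result`: `selected_indices`, `rmsecv_path`,
#'   `n_vars_path`, `coef_paths` (runs x p matrix of coefficients, 0 for
#'   dropped variables), `best_run`, `seed`.
#' @export
cars_select <- function(X, y, total_runs = 50L, n_folds = 10L,
                        max_components = 10L, mc_fraction = 0.8,
                        seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) {
    stop_beefhsi("cars_select needs >= 2 predictors",
                 class = "beefhsi_value_error")
  }
  if (n < 2L * n_folds) {
    stop_beefhsi("cars_select needs n >= 2 * n_folds",
                 class = "beefhsi_value_error")
  }
  run_seeds <- derive_seeds(seed, 2L * total_runs + 1L)
  retained <- seq_len(p)
  rmsecv_path <- rep(NA_real_, total_runs)
  n_vars_path <- rep(NA_integer_, total_runs)
  coef_paths <- matrix(0, total_runs, p)
  sets <- vector("list", total_runs)
  n_mc <- max(2L, round(mc_fraction * n))
  runs_done <- 0L
  for (j in seq_len(total_runs)) {
    if (length(retained) < 2L) {
      warning(sprintf("CARS retained set collapsed at run %d; schedule truncated", j))
      break
    }
    sub <- with_seed(run_seeds[2L * j - 1L], sample.int(n, n_mc))
    ncomp <- min(max_components, length(retained), n_mc - 1L)
    m <- fit_pls(X[sub, retained, drop = FALSE], y[sub], ncomp)
    w <- abs(m$coef)
    if (sum(w) == 0) w <- rep(1, length(w))
    w <- w / sum(w)
    # the schedule's target count at this run; the ARS draw count equals it,
    # so the realized variable-count trajectory tracks the EDF curve
    edf_n <- max(2L, round(edf_ratio(j, total_runs, p) * p))
    keep_n <- min(length(retained), edf_n)
    # EDF forced cut: top-weighted variables, ties to the lower band index
    ord <- order(-w, retained)
    edf_set <- retained[ord[seq_len(keep_n)]]
    edf_w <- w[match(edf_set, retained)]
    # adaptive reweighted sampling: weighted draw with replacement
    drawn <- with_seed(run_seeds[2L * j],
                       sample(edf_set, size = edf_n, replace = TRUE,
                              prob = edf_w))
    retained <- sort(unique(drawn))
    if (length(retained) < 2L) retained <- sort(edf_set[order(-edf_w)][1:2])
    ncomp_cv <- min(max_components, length(retained), n - 1L)
    rmsecv_path[j] <- rmsecv(X[, retained, drop = FALSE], y, ncomp_cv,
                             n_folds = n_folds, seed = run_seeds[2L * total_runs + 1L])
    n_vars_path[j] <- length(retained)
    mm <- fit_pls(X[, retained, drop = FALSE], y, ncomp_cv)
    coef_paths[j, retained] <- mm$coef
    sets[[j]] <- retained
    runs_done <- j
  }
  if (runs_done == 0L) {
    stop_beefhsi("CARS made no sampling runs", class = "beefhsi_value_error")
  }
  best <- which.min(rmsecv_path[seq_len(runs_done)])
  structure(list(selected_indices = sets[[best]],
                 rmsecv_path = rmsecv_path[seq_len(runs_done)],
                 n_vars_path = n_vars_path[seq_len(runs_done)],
                 coef_paths = coef_paths[seq_len(runs_done), , drop = FALSE],
                 best_run = best, seed = seed,
                 sets = sets[seq_len(runs_done)]),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d wavelengths selected at run %d (RMSECV %.4f)\n",
              length(x$selected_indices), x$best_run,
              x$rmsecv_path[x$best_run]))
  invisible(x)
}

#' Per-tissue CARS wavelength selection
#'
#' Runs CARS independently on the muscle rows and the fat rows of a
#' [spectral_dataset], against the ordinal class response 1-4.
#'
#' @param dataset a [spectral_dataset] with muscle/fat tissue tags.
#' @param total_runs,n_folds,max_components,seed passed to [cars_select()];
#'   the per-tissue seeds are derived from `seed`.
#' @return named list (`muscle`, `fat`) of `cars_result`s; tissues with too
#'   few rows are skipped with a warning.
#' @export
select_per_tissue <- function(dataset, total_runs = 50L, n_folds = 10L,
                              max_components = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  seeds <- derive_seeds(seed, 2L)
  out <- list()
  for (k in c("muscle", "fat")) {
    rows <- which(dataset$tissue == k)
    if (length(rows) < 2L * n_folds) {
      warning(sprintf("tissue '%s' has too few rows (%d); skipped", k,
                      length(rows)))
      next
    }
    out[[k]] <- cars_select(dataset$X[rows, , drop = FALSE],
                            class_code(dataset$y[rows]),
                            total_runs = total_runs, n_folds = n_folds,
                            max_components = max_components,
                            seed = seeds[match(k, c("muscle", "fat"))])
  }
  out
}
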