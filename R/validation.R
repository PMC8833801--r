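#' Fit the full selection + regression pipeline on one dataset
#'
#' Convenience wrapper running the complete training procedure: bootstrap-
#' forest ranking, top-k selection, adaptive-lasso fit on the selected
#' features. This is the unit repeated inside LOOCV folds and permutation
#' replicates.
#'
#' @param x Feature matrix (subjects x features).
#' @param y Motility response.
#' @param k Number of top-ranked features passed to the lasso.
#' @param n_trees,n_repeats Forest settings ([bootstrap_forest_rank()]).
#' @param criterion Lambda selection rule ([adaptive_lasso_fit()]).
#' @param gamma Adaptive weight exponent.
#' @param seed Seed for the ranking stage.
#' @return A list with `model` (`adaptive_lasso`), `selected` (character),
#'   `ranking` (`ranked_features`) and in-sample `fitted`, `r2`, `rmse`.
#' @export
fit_motility_model <- function(x, y, k = 10, n_trees = 100, n_repeats = 10,
                               criterion = "aicc", gamma = 1, seed = 1L) {
  x <- as.matrix(x)
  ranking <- bootstrap_forest_rank(x, y, n_trees = n_trees,
                                   n_repeats = n_repeats, seed = seed)
  selected <- select_top_k(ranking, k = min(k, ncol(x)))
  model <- adaptive_lasso_fit(x[, selected, drop = FALSE], y,
                              gamma = gamma, criterion = criterion)
  fitted <- predict(model, x)
  list(
    model = model, selected = selected, ranking = ranking,
    fitted = fitted,
    # a fully shrunk (intercept-only) model explains nothing
    r2 = if (sd(fitted) > 0) fit_line_r2(fitted, y) else 0,
    rmse = sqrt(mean((fitted - y)^2))
  )
}

#' Baseline leave-one-out RMSE of the mean predictor
#'
#' For each held-out subject the prediction is the mean motility of the
#' remaining subjects; returns the RMSE of those predictions.
#'
#' @param y Numeric response vector (n >= 2).
#' @return RMSE in the units of `y`.
#' @examples
#' baseline_loocv_rmse(c(0, 0, 3)) # sqrt(4.5)
#' @export
baseline_loocv_rmse <- function(y) {
  n <- length(y)
  if (n < 2) stop("at least 2 observations are required")
  pred <- (sum(y) - y) / (n - 1)
  sqrt(mean((pred - y)^2))
}

#' R-squared of the fitted line between predictions and observations
#'
#' The squared Pearson correlation between predicted and actual values,
#' i.e. the R^2 of the OLS line fitted through the scatter.
#'
#' @param predicted,actual Numeric vectors (>= 3 pairs; `predicted` must
#'   not be constant).
#' @return Fraction in \[0, 1\].
#' @export
fit_line_r2 <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  if (length(predicted) < 3) stop("at least 3 pairs are required")
  if (sd(predicted) == 0) {
    stop("constant predictions: the fitted line is undefined")
  }
  cor(predicted, actual)^2
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' For each subject, the full pipeline (forest ranking, top-k selection,
#' adaptive lasso) is retrained on the remaining n - 1 subjects and the
#' held-out subject is predicted, so feature selection never sees the test
#' subject. Per-fold RNG streams derive from the master seed, making any
#' fold reproducible in isolation.
#'
#' @inheritParams fit_motility_model
#' @param seed Master seed fanned out to the folds.
#' @return A `cv_result` list: `predictions` (out-of-fold, one per
#'   subject), `loocv_rmse`, `baseline_rmse`, `r2_fitted_line`,
#'   `fold_selected` (list), `fold_nnz` (integer vector).
#' @export
loocv_evaluate <- function(x, y, k = 10, n_trees = 100, n_repeats = 10,
                           criterion = "aicc", gamma = 1, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("LOOCV requires at least 3 subjects")
  set.seed(as.integer(seed))
  fold_seeds <- sample.int(.Machine$integer.max, n)
  preds <- numeric(n)
  fold_selected <- vector("list", n)
  fold_nnz <- integer(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      fit_motility_model(x[-i, , drop = FALSE], y[-i], k = k,
                         n_trees = n_trees, n_repeats = n_repeats,
                         criterion = criterion, gamma = gamma,
                         seed = fold_seeds[i]),
      error = function(e) {
        stop(sprintf("LOOCV fold %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
    preds[i] <- predict(res$model, x[i, , drop = FALSE])
    fold_selected[[i]] <- names(which(res$model$coefficients != 0))
    fold_nnz[i] <- length(fold_selected[[i]])
  }
  structure(
    list(
      predictions = preds,
      loocv_rmse = sqrt(mean((preds - y)^2)),
      baseline_rmse = baseline_loocv_rmse(y),
      r2_fitted_line = if (sd(preds) > 0) fit_line_r2(preds, y) else NA_real_,
      fold_selected = fold_selected,
      fold_nnz = fold_nnz,
      n_folds = n
    ),
    class = "cv_result"
  )
}

perm_pvalue <- function(null_stats, observed, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  hits <- if (tail == "greater") sum(null_stats >= observed) else {
    sum(null_stats <= observed)
  }
  (1 + hits) / (length(null_stats) + 1)
}

#' Permutation test of the feature-motility association
#'
#' Fits the full training procedure (selection + adaptive lasso) on the
#' true motility to obtain the observed in-sample fitted-line R^2 and RMSE,
#' then refits the identical procedure on `n_perm` random permutations of
#' the motility vector. Empirical p-values use the add-one estimator, so
#' they are never exactly zero.
#'
#' @inheritParams fit_motility_model
#' @param n_perm Number of permutations (>= 10).
#' @param statistic Use the in-sample full-data fit (default) or the LOOCV
#'   out-of-fold statistics for both observed and null models.
#' @return A `permutation_result` list: `null_r2`, `null_rmse`,
#'   `observed_r2`, `observed_rmse`, `p_r2`, `p_rmse`, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, y, n_perm = 2000, seed = 1L, k = 10,
                             n_trees = 100, n_repeats = 10,
                             criterion = "aicc", gamma = 1,
                             statistic = c("in_sample", "loocv")) {
  statistic <- match.arg(statistic)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("permutation test requires at least 5 subjects")
  if (n_perm < 10) stop("n_perm must be at least 10")
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max, n_perm + 1L)
  # one procedure seed shared by the observed fit and every scramble: the
  # identical (bitwise) training procedure is applied to each response
  # ordering, so only the permutation varies between replicates
  proc_seed <- perm_seeds[1]
  eval_once <- function(yy, sd_) {
    if (statistic == "in_sample") {
      res <- fit_motility_model(x, yy, k = k, n_trees = n_trees,
                                n_repeats = n_repeats, criterion = criterion,
                                gamma = gamma, seed = sd_)
      fitted <- res$fitted
      r2 <- if (sd(fitted) > 0) fit_line_r2(fitted, yy) else 0
      c(r2 = r2, rmse = sqrt(mean((fitted - yy)^2)))
    } else {
      cv <- loocv_evaluate(x, yy, k = k, n_trees = n_trees,
                           n_repeats = n_repeats, criterion = criterion,
                           gamma = gamma, seed = sd_)
      r2 <- if (!is.na(cv$r2_fitted_line)) cv$r2_fitted_line else 0
      c(r2 = r2, rmse = cv$loocv_rmse)
    }
  }
  obs <- eval_once(y, proc_seed)
  null_stats <- matrix(NA_real_, n_perm, 2)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b + 1L])
    yp <- y[sample.int(n)]
    null_stats[b, ] <- eval_once(yp, proc_seed)
  }
  structure(
    list(
      null_r2 = null_stats[, 1], null_rmse = null_stats[, 2],
      observed_r2 = unname(obs["r2"]), observed_rmse = unname(obs["rmse"]),
      p_r2 = perm_pvalue(null_stats[, 1], obs["r2"], "greater"),
      p_rmse = perm_pvalue(null_stats[, 2], obs["rmse"], "less"),
      n_perm = n_perm, seed = seed, statistic = statistic
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<permutation_result> %d permutations (%s statistic)\n",
           "  observed R2 %.3f (p = %.4g), RMSE %.3f (p = %.4g)\n"),
    x$n_perm, x$statistic, x$observed_r2, x$p_r2, x$observed_rmse, x$p_rmse
  ))
  invisible(x)
}
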