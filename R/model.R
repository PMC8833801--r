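#' Rank features with a repeated bootstrap forest
#'
#' Trains `n_repeats` regression forests (each: `n_trees` trees on bootstrap
#' resamples with sqrt(p) feature subsampling and variance-reduction splits)
#' and ranks features by their impurity-decrease importance averaged over
#' repeats. Repeating the forest averages out the bootstrap randomness of a
#' single ranking. Ties are broken by feature name.
#'
#' @param x Numeric matrix or data.frame of predictors (subjects x features).
#' @param y Numeric response (tumor mean motility, um^2/min).
#' @param n_trees Trees per forest.
#' @param n_repeats Forest repeats averaged into the final score.
#' @param mtry Features tried per split; defaults to sqrt(p).
#' @param seed Integer seed (ranking is deterministic given it).
#' @return A `ranked_features` list with `features` (ordered names),
#'   `scores` and `n_repeats`.
#' @export
bootstrap_forest_rank <- function(x, y, n_trees = 100, n_repeats = 10,
                                  seed = 1L, mtry = NULL) {
  x <- as.data.frame(x)
  if (nrow(x) < 5) stop("at least 5 subjects are required for ranking")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (var(y) == 0) stop("constant response: feature ranking is undefined")
  if (is.null(colnames(x)) || any(colnames(x) == "")) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  orig_names <- colnames(x)
  dat <- cbind(x, .response = y)
  names(dat) <- c(paste0("f", seq_along(orig_names)), ".response")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_repeats)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  imp <- matrix(0, p, n_repeats, dimnames = list(names(dat)[seq_len(p)], NULL))
  for (r in seq_len(n_repeats)) {
    fit <- ranger::ranger(
      dependent.variable.name = ".response", data = dat,
      num.trees = n_trees, mtry = mtry,
      importance = "impurity", replace = TRUE, num.threads = 1,
      seed = rep_seeds[r]
    )
    imp[, r] <- fit$variable.importance[rownames(imp)]
  }
  scores <- rowMeans(imp)
  names(scores) <- orig_names
  ord <- order(-scores, orig_names)
  structure(
    list(features = orig_names[ord], scores = scores[ord],
         n_repeats = n_repeats),
    class = "ranked_features"
  )
}

#' Keep the top-ranked features
#'
#' @param ranked A [bootstrap_forest_rank()] result.
#' @param k Number of features to keep (default 10).
#' @return Character vector: the first `k` names in rank order.
#' @export
select_top_k <- function(ranked, k = 10) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (k < 1) stop("k must be at least 1")
  if (k > length(ranked$features)) {
    stop("k exceeds the number of ranked features")
  }
  ranked$features[seq_len(k)]
}

soft_threshold <- function(z, t) sign(z) * pmax(0, abs(z) - t)

# weighted-lasso solutions along a decreasing lambda grid (warm starts),
# via C++ cyclic coordinate descent on the Gram formulation; the lambda = 0
# entry is replaced by the exact unpenalised least-squares limit on the
# finite-weight support (infinite-weight coefficients stay pinned at 0)
lasso_path <- function(xs, yc, w, grid) {
  n <- nrow(xs)
  g <- crossprod(xs) / n
  xty <- as.vector(crossprod(xs, yc) / n)
  betas <- cpp_cd_lasso_path(g, xty, w, grid)
  zero <- which(grid == 0)
  if (length(zero)) {
    finite <- is.finite(w)
    b <- numeric(ncol(xs))
    gf <- g[finite, finite, drop = FALSE]
    if (kappa(gf, exact = TRUE) > 1e10) {
      gf <- gf + diag(1e-8, nrow(gf))
    }
    b[finite] <- solve(gf, xty[finite])
    betas[, zero] <- b
  }
  betas
}

#' Fit an adaptive lasso regression
#'
#' Weighted-L1 regression with oracle-style weights from a pilot fit:
#' features are standardised internally, a pilot OLS estimate gives weights
#' `w_j = 1 / |beta_pilot_j|^gamma`, and the weighted lasso is solved by
#' cyclic coordinate descent with soft-thresholding over a 100-point
#' logarithmic lambda grid spanning four decades below `lambda_max` (the
#' smallest penalty that zeroes every coefficient), plus the unpenalised
#' solution. The reported model uses the lambda minimising the selection
#' criterion (AICc by default; BIC and inner leave-one-out CV available).
#' If the pilot design is near-singular (condition number > 1e10) the
#' pilot falls back to a lightly ridged estimate.
#'
#' @param x Numeric matrix/data.frame of predictors (p < n).
#' @param y Numeric response.
#' @param gamma Adaptive-weight exponent (default 1).
#' @param lambda Optional user lambda values (overrides the grid).
#' @param criterion `"aicc"`, `"bic"` or `"inner_loocv"`.
#' @param nlambda,lambda_min_ratio Grid size and span.
#' @return An `adaptive_lasso` model: `intercept`, `coefficients` (raw
#'   scale; exact zeros for eliminated features), `weights`, `pilot`,
#'   `gamma`, `lambda`, `lambda_grid`, `nnz_path`, `criterion`,
#'   standardisation constants, and naive post-selection `p_values`.
#' @examples
#' x <- matrix(rnorm(200), 40)
#' y <- x[, 1] * 2 + rnorm(40, sd = 0.1)
#' fit <- adaptive_lasso_fit(x, y)
#' @export
adaptive_lasso_fit <- function(x, y, gamma = 1, lambda = NULL,
                               criterion = c("aicc", "bic", "inner_loocv"),
                               nlambda = 100L, lambda_min_ratio = 1e-4) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (p >= n) stop("adaptive lasso requires p < n for the OLS pilot")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  xm <- colMeans(x)
  xs_sd <- sqrt(colMeans(sweep(x, 2, xm)^2))
  if (any(xs_sd == 0)) {
    stop("zero-variance features cannot be standardised: ",
         paste(colnames(x)[xs_sd == 0], collapse = ", "))
  }
  xs <- sweep(sweep(x, 2, xm), 2, xs_sd, "/")
  ym <- mean(y)
  yc <- y - ym

  # pilot OLS (ridge fallback for ill-conditioned designs)
  xtx <- crossprod(xs) / n
  cond <- kappa(xtx, exact = TRUE)
  ridged <- FALSE
  if (cond > 1e10) {
    ridged <- TRUE
    pilot <- solve(xtx + diag(1e-4, p), crossprod(xs, yc) / n)
  } else {
    pilot <- solve(xtx, crossprod(xs, yc) / n)
  }
  pilot <- as.vector(pilot)
  w <- 1 / abs(pilot)^gamma # Inf where the pilot is exactly zero

  finite <- is.finite(w)
  if (!any(finite)) stop("all pilot coefficients are zero")
  lambda_max <- max(abs(crossprod(xs[, finite, drop = FALSE], yc)) /
                      (n * w[finite]))
  grid <- if (is.null(lambda)) {
    c(exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
              length.out = nlambda)), 0)
  } else {
    sort(unique(as.numeric(lambda)), decreasing = TRUE)
  }

  betas <- lasso_path(xs, yc, w, grid)
  nnz <- colSums(betas != 0)
  rss <- colSums((as.vector(yc) - xs %*% betas)^2)

  crit <- switch(criterion,
    aicc = {
      # k counts the intercept and the error variance along with the
      # active coefficients (Hurvich-Tsai small-sample correction)
      k <- nnz + 2
      ifelse(n - k - 1 > 0,
             n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
             Inf)
    },
    bic = n * log(rss / n) + (nnz + 1) * log(n),
    inner_loocv = {
      errs <- matrix(NA_real_, n, length(grid))
      for (i in seq_len(n)) {
        bi <- lasso_path(xs[-i, , drop = FALSE], yc[-i], w, grid)
        errs[i, ] <- (yc[i] - as.vector(xs[i, ] %*% bi))^2
      }
      colMeans(errs)
    }
  )
  best <- which.min(crit)
  beta_std <- betas[, best]
  beta_raw <- beta_std / xs_sd
  intercept <- ym - sum(beta_raw * xm)

  # naive post-selection OLS t-tests on the selected support
  sel <- which(beta_std != 0)
  p_values <- setNames(rep(NA_real_, p), colnames(x))
  if (length(sel) && length(sel) < n - 1) {
    ols <- lm(y ~ x[, sel, drop = FALSE])
    # suppress the "essentially perfect fit" note on noiseless designs;
    # these p-values are labelled naive either way. Aliased (perfectly
    # collinear) columns are dropped by lm and stay NA here.
    aliased <- is.na(coef(ols))[-1]
    pv <- suppressWarnings(summary(ols)$coefficients[-1, 4])
    p_values[sel[!aliased]] <- pv
  }
  structure(
    list(
      intercept = intercept,
      coefficients = setNames(beta_raw, colnames(x)),
      coefficients_std = setNames(beta_std, colnames(x)),
      weights = setNames(w, colnames(x)),
      pilot = setNames(pilot, colnames(x)),
      gamma = gamma, lambda = grid[best], lambda_grid = grid,
      nnz_path = nnz, criterion = criterion, ridged_pilot = ridged,
      standardization = list(xm = xm, xs = xs_sd, ym = ym),
      p_values = p_values
    ),
    class = "adaptive_lasso"
  )
}

#' Predict motility from an adaptive-lasso model
#'
#' @param object An `adaptive_lasso` model.
#' @param newdata Matrix/data.frame containing at least the model's
#'   features (matched by name), or a named vector for one subject.
#' @param ... Unused.
#' @return Numeric vector of predicted motility (um^2/min).
#' @export
predict.adaptive_lasso <- function(object, newdata, ...) {
  feats <- names(object$coefficients)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing)) {
    stop("missing features in newdata: ", paste(missing, collapse = ", "))
  }
  as.vector(object$intercept +
              newdata[, feats, drop = FALSE] %*% object$coefficients)
}

#' @export
print.adaptive_lasso <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  cat(sprintf(
    "<adaptive_lasso> %d of %d features retained (lambda = %.4g, %s)\n",
    length(nz), length(x$coefficients), x$lambda, x$criterion
  ))
  if (length(nz)) print(signif(nz, 4))
  invisible(x)
}
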