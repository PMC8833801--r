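make_xy <- function(n = 31, p = 10, seed = 1, beta = c(10, rep(0, 9)),
                    noise = 0.01) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.vector(x %*% beta) + rnorm(n, sd = noise)
  list(x = x, y = y)
}

test_that("a dominant signal feature is ranked first almost always", {
  hits <- vapply(1:20, function(s) {
    d <- make_xy(seed = s)
    r <- bootstrap_forest_rank(d$x, d$y, seed = s)
    r$features[1] == "f1"
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("duplicating a column splits its importance roughly in half", {
  # with every feature available at each split (mtry = p), a duplicated
  # column shares the original's impurity credit instead of adding to it;
  # at the default mtry = sqrt(p) the duplicate also raises the family's
  # split availability, which confounds the accounting
  d <- make_xy(seed = 4, beta = c(8, 3, rep(0, 8)), noise = 0.5)
  r1 <- bootstrap_forest_rank(d$x, d$y, n_repeats = 30, seed = 2, mtry = 10)
  x2 <- cbind(d$x, f1_copy = d$x[, "f1"])
  r2 <- bootstrap_forest_rank(x2, d$y, n_repeats = 30, seed = 2, mtry = 11)
  solo <- r1$scores["f1"]
  pair <- r2$scores["f1"] + r2$scores["f1_copy"]
  expect_lt(abs(pair - solo) / solo, 0.2)
  # the two copies share the credit nearly evenly
  expect_equal(unname(r2$scores["f1"] / pair), 0.5, tolerance = 0.15)
})

test_that("ranking is deterministic in the seed and rejects bad input", {
  d <- make_xy(seed = 9)
  r1 <- bootstrap_forest_rank(d$x, d$y, seed = 33)
  r2 <- bootstrap_forest_rank(d$x, d$y, seed = 33)
  expect_identical(r1$features, r2$features)
  expect_identical(r1$scores, r2$scores)
  expect_error(bootstrap_forest_rank(d$x, rep(1, 31)), "constant")
  expect_error(bootstrap_forest_rank(d$x[1:4, ], d$y[1:4]), "5 subjects")
})

test_that("select_top_k returns the ranking prefix", {
  d <- make_xy(seed = 5)
  r <- bootstrap_forest_rank(d$x, d$y, seed = 5)
  expect_identical(select_top_k(r, 10), r$features[1:10])
  expect_identical(select_top_k(r, ncol(d$x)), r$features)
  expect_error(select_top_k(r, 0), "at least 1")
  expect_error(select_top_k(r, 99), "exceeds")
})

test_that("lambda = 0 reproduces ordinary least squares", {
  d <- make_xy(n = 40, p = 6, seed = 7, beta = c(2, -1, 0.5, 0, 0, 0),
               noise = 0.3)
  fit <- adaptive_lasso_fit(d$x, d$y, lambda = 0)
  ols <- lm(d$y ~ d$x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("lambda >= lambda_max shrinks everything to the intercept", {
  d <- make_xy(n = 35, p = 5, seed = 8, beta = c(1, 2, 0, 0, 0), noise = 0.5)
  fit <- adaptive_lasso_fit(d$x, d$y)
  big <- adaptive_lasso_fit(d$x, d$y, lambda = max(fit$lambda_grid) * 1.01)
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, mean(d$y))
  pred <- predict(big, d$x)
  expect_true(all(pred == mean(d$y)))
})

test_that("orthonormal designs obey the soft-threshold closed form", {
  set.seed(10)
  n <- 32; p <- 6
  raw <- matrix(rnorm(n * p), n, p)
  q <- qr.Q(qr(scale(raw, scale = FALSE)))[, 1:p] * sqrt(n)
  q <- scale(q, scale = FALSE) # mean-zero, X'X / n = I
  colnames(q) <- paste0("f", 1:p)
  y <- as.vector(q %*% c(1.5, -0.8, 0.4, 0.1, 0, 0)) + rnorm(n, sd = 0.2)
  bhat <- as.vector(crossprod(q, y - mean(y)) / n) # pilot OLS
  w <- 1 / abs(bhat)
  for (lam in c(0.001, 0.01, 0.05)) {
    fit <- adaptive_lasso_fit(q, y, lambda = lam)
    closed <- sign(bhat) * pmax(0, abs(bhat) - lam * w)
    got <- fit$coefficients_std
    expect_equal(unname(got), closed, tolerance = 1e-10)
  }
})

test_that("agrees with glmnet as an independent weighted-lasso oracle", {
  skip_if_not_installed("glmnet")
  d <- make_xy(n = 45, p = 8, seed = 12,
               beta = c(3, -2, 1, 0.5, rep(0, 4)), noise = 1)
  # use the package's own pilot weights so both solvers see one problem
  fit0 <- adaptive_lasso_fit(d$x, d$y)
  w <- fit0$weights
  lam <- 0.03
  fit <- adaptive_lasso_fit(d$x, d$y, lambda = lam)
  xs <- scale(d$x, scale = apply(d$x, 2, function(c_) {
    sqrt(mean((c_ - mean(c_))^2))
  }))
  gl <- glmnet::glmnet(
    xs, d$y, alpha = 1, standardize = FALSE, intercept = TRUE,
    penalty.factor = w, lambda = lam * sum(w) / length(w),
    thresh = 1e-14
  )
  expect_equal(unname(fit$coefficients_std),
               as.vector(coef(gl))[-1], tolerance = 1e-6)
})

test_that("the active set shrinks monotonically along the lambda grid", {
  for (s in 1:5) {
    d <- make_xy(n = 31, p = 10, seed = s,
                 beta = c(1, -1, 0.7, -0.7, rep(0, 6)), noise = 1)
    fit <- adaptive_lasso_fit(d$x, d$y)
    grid_nnz <- fit$nnz_path[fit$lambda_grid > 0]
    expect_true(all(diff(grid_nnz) >= 0)) # grid is decreasing in lambda
  }
})

test_that("adaptive lasso has near-oracle selection on independent designs", {
  # study-scale conditions: n = 31, 4 true + 6 null features, R2 = 0.6
  stats <- vapply(1:40, function(s) {
    set.seed(s + 1000)
    n <- 31
    x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
    beta <- c(1, -1, -0.7, 0.7, rep(0, 6))
    mu <- as.vector(scale(x) %*% beta)
    mu <- mu * sqrt(0.6) * 1.25 / sd(mu)
    y <- 2.24 + mu + rnorm(n, sd = sqrt(var(mu) * (1 / 0.6 - 1)))
    m <- adaptive_lasso_fit(x, y)
    keep <- m$coefficients != 0
    signs_ok <- all(sign(m$coefficients[1:4][keep[1:4]]) ==
                      sign(beta[1:4][keep[1:4]]))
    c(planted = sum(keep[1:4]), decoys = sum(keep[5:10]), signs = signs_ok)
  }, numeric(3))
  # planted features are retained far more often than null features
  expect_gt(mean(stats["planted", ]) / 4, 0.8)
  expect_lt(mean(stats["decoys", ]) / 6, 0.4)
  # recovered coefficient signs match the planted signs
  expect_gte(mean(stats["signs", ]), 0.95)
})

test_that("prediction is affine and errors on missing features", {
  d <- make_xy(n = 31, p = 4, seed = 13, beta = c(1, 2, 0, 0), noise = 0.2)
  fit <- adaptive_lasso_fit(d$x, d$y)
  p1 <- predict(fit, d$x[1, ])
  p2 <- predict(fit, d$x[2, ])
  pm <- predict(fit, (d$x[1, ] + d$x[2, ]) / 2)
  expect_equal(pm, (p1 + p2) / 2, tolerance = 1e-12)
  expect_error(predict(fit, d$x[, 1:2]), "missing features.*f3")
  # training rows reproduce in-sample fitted values
  expect_equal(predict(fit, d$x),
               as.vector(fit$intercept + d$x %*% fit$coefficients))
})

test_that("collinear pilots fall back to ridge with a flag", {
  set.seed(14)
  n <- 30
  x1 <- rnorm(n)
  x <- cbind(f1 = x1, f2 = x1 + rnorm(n, sd = 1e-9), f3 = rnorm(n))
  y <- x1 + rnorm(n, sd = 0.1)
  fit <- adaptive_lasso_fit(x, y)
  expect_true(fit$ridged_pilot)
  expect_true(all(is.finite(fit$coefficients)))
})
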