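test_that("MSD matches the all-pairs brute-force oracle exactly", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 10
    t <- (0:(n - 1)) * 15
    x <- cumsum(rnorm(n))
    y <- cumsum(rnorm(n))
    got <- compute_msd(data.frame(t_min = t, x_um = x, y_um = y))
    want <- oracle_msd(t, x, y)
    expect_equal(got$msd, want$msd, tolerance = 1e-12)
    expect_equal(got$lags, want$lags)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("a hand-enumerated 5-point track reproduces its MSD", {
  # positions (0,0), (1,0), (1,1), (3,1), (3,4) at t = 0, 15, ..., 60
  tr <- data.frame(t_min = seq(0, 60, 15),
                   x_um = c(0, 1, 1, 3, 3), y_um = c(0, 0, 1, 1, 4))
  msd <- compute_msd(tr)
  # lag 1: (1 + 1 + 4 + 9) / 4; lag 2: (2 + 5 + 13) / 3;
  # lag 3: (10 + 20) / 2; lag 4: 25
  expect_equal(msd$msd, c(15 / 4, 20 / 3, 15, 25), tolerance = 1e-12)
  expect_equal(msd$n_pairs, c(4L, 3L, 2L, 1L))
})

test_that("ballistic and stationary tracks give exact MSD identities", {
  n <- 20
  t <- (0:(n - 1)) * 15
  v <- 0.3
  straight <- data.frame(t_min = t, x_um = v * t, y_um = 0)
  msd <- compute_msd(straight)
  expect_equal(msd$msd, (v * msd$lags)^2, tolerance = 1e-12)
  still <- data.frame(t_min = t, x_um = rep(1, n), y_um = rep(2, n))
  expect_true(all(compute_msd(still)$msd == 0))
})

test_that("track validation rejects malformed inputs", {
  expect_error(
    compute_msd(data.frame(t_min = c(0, 15), x_um = 0:1, y_um = 0:1)),
    "3 time points"
  )
  expect_error(
    compute_msd(data.frame(t_min = c(0, 15, 15), x_um = 1:3, y_um = 1:3)),
    "strictly increasing"
  )
  expect_error(
    compute_msd(data.frame(t_min = c(0, 10, 25), x_um = 1:3, y_um = 1:3)),
    "uniform"
  )
  expect_error(
    compute_msd(data.frame(t_min = c(0, 15, 30), x_um = c(1, NA, 3),
                           y_um = 1:3)),
    "finite"
  )
})

test_that("fit_rmc recovers the coefficient from exact linear MSD", {
  lags <- 15 * (1:16)
  msd <- structure(
    list(lags = lags, msd = 4 * 2.24 * lags, n_pairs = 64 - (1:16) + 0,
         dt = 15),
    class = "msd_curve"
  )
  expect_equal(fit_rmc(msd)$rmc, 2.24, tolerance = 1e-12)
  msd0 <- structure(
    list(lags = lags, msd = rep(0, 16), n_pairs = rep(10L, 16), dt = 15),
    class = "msd_curve"
  )
  expect_equal(fit_rmc(msd0)$rmc, 0)
})

test_that("negative MSD slopes are floored at zero and flagged", {
  lags <- 15 * (1:8)
  msd <- structure(
    list(lags = lags, msd = -4 * lags, n_pairs = rep(10L, 8), dt = 15),
    class = "msd_curve"
  )
  fit <- fit_rmc(msd)
  expect_equal(fit$rmc, 0)
  expect_true(fit$floored)
})

test_that("simulation-based recovery: fitted RMC is unbiased at D = 1", {
  cfg <- track_sim_config(n_cells = 10000, rmc_true = 1,
                          stiffness_labels = 0.7)
  tr <- simulate_tracks(cfg, seed = 77)
  est <- estimate_motility(tr)
  expect_equal(mean(est$cells$rmc), 1, tolerance = 0.02)
})

test_that("the PRW model fit recovers D from a noiseless PRW curve", {
  lags <- 15 * (1:30)
  d <- 1.8; p <- 45
  msd <- structure(
    list(lags = lags, msd = 4 * d * (lags - p * (1 - exp(-lags / p))),
         n_pairs = rep(50L, 30), dt = 15),
    class = "msd_curve"
  )
  fit <- fit_rmc(msd, model = "prw")
  expect_equal(fit$rmc, d, tolerance = 1e-3)
  expect_equal(fit$persistence_time, p, tolerance = 1e-2)
})

test_that("brownian_linear RMC is scale-equivariant in position units", {
  set.seed(3)
  n <- 30
  tr <- data.frame(t_min = (0:(n - 1)) * 15, x_um = cumsum(rnorm(n)),
                   y_um = cumsum(rnorm(n)))
  base <- fit_rmc(compute_msd(tr))$rmc
  for (c_ in c(0.5, 2, 7)) {
    tr2 <- transform(tr, x_um = c_ * x_um, y_um = c_ * y_um)
    expect_equal(fit_rmc(compute_msd(tr2))$rmc, c_^2 * base,
                 tolerance = 1e-10)
  }
})

test_that("subject mean pools cells across conditions unweighted", {
  est <- data.frame(rmc = c(1, 2, 3), stiffness_kpa = c(0.7, 0.7, 4.6))
  expect_equal(subject_mean_motility(est)$tumor_mean, 2)
  # equal per-cell values across 6 conditions leave the mean unchanged
  est6 <- data.frame(rmc = rep(1.7, 60),
                     stiffness_kpa = rep(c(0.7, 4.6, 9.3, 19.5, 100, 200),
                                         each = 10))
  expect_equal(subject_mean_motility(est6)$tumor_mean, 1.7)
  expect_error(subject_mean_motility(data.frame()), "no cell")
})

test_that("the per-condition cell-count rule flags under-sampled subjects", {
  est <- data.frame(rmc = rnorm(49, 2), stiffness_kpa = rep(c(1, 2), c(24, 25)))
  expect_true(subject_mean_motility(est, enforce_min_cells = TRUE)$excluded)
  est_ok <- data.frame(rmc = rnorm(50, 2), stiffness_kpa = rep(c(1, 2), 25))
  expect_false(subject_mean_motility(est_ok, enforce_min_cells = TRUE)$excluded)
  expect_false(subject_mean_motility(est)$excluded)
})

test_that("batch motility estimation equals the per-track path", {
  cfg <- track_sim_config(n_cells = 4, rmc_true = 1.3)
  tr <- simulate_tracks(cfg, seed = 21)
  est <- estimate_motility(tr) # uniform grid: vectorised path
  for (cid in unique(tr$cell_id)[c(1, 8, 17)]) {
    one <- tr[tr$cell_id == cid, ]
    expect_equal(
      est$cells$rmc[est$cells$cell_id == cid],
      fit_rmc(compute_msd(one))$rmc,
      tolerance = 1e-12
    )
  }
  expect_equal(est$subjects$tumor_mean, mean(est$cells$rmc))
})
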