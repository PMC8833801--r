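#' Mean squared displacement of a single cell track
#'
#' Computes the time-averaged MSD curve over overlapping windows: for each
#' lag `tau = m * dt`, the average of `|r(t + tau) - r(t)|^2` over all
#' overlapping start times in the track.
#'
#' @param track A data.frame for one cell with columns `t_min`, `x_um`,
#'   `y_um` (additional columns ignored). Times must be strictly increasing
#'   and uniformly spaced.
#' @param max_lag_fraction Largest lag as a fraction of the available
#'   `(n_frames - 1)` lags, in (0, 1].
#' @return An `msd_curve` list with `lags` (min), `msd` (um^2), `n_pairs`
#'   and `dt`.
#' @examples
#' tr <- simulate_tracks(track_sim_config(n_cells = 1, rmc_true = 1), seed = 1)
#' msd <- compute_msd(tr[tr$cell_id == 1 & tr$stiffness_kpa == 0.7, ])
#' @export
compute_msd <- function(track, max_lag_fraction = 1) {
  if (!is.data.frame(track)) stop("track must be a data.frame")
  need <- c("t_min", "x_um", "y_um")
  if (!all(need %in% names(track))) {
    stop("track must have columns t_min, x_um, y_um")
  }
  msd_core(track$t_min, track$x_um, track$y_um, max_lag_fraction)
}

msd_core <- function(t, x, y, max_lag_fraction = 1) {
  n <- length(t)
  if (n < 3L) stop("track must have at least 3 time points")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("track coordinates and times must be finite")
  }
  dts <- diff(t)
  if (any(dts <= 0)) stop("track times must be strictly increasing")
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    stop("track times must be uniformly spaced")
  }
  if (!is.finite(max_lag_fraction) || max_lag_fraction <= 0 ||
      max_lag_fraction > 1) {
    stop("max_lag_fraction must be in (0, 1]")
  }
  kmax <- max(1L, as.integer(floor(max_lag_fraction * (n - 1))))
  msd <- numeric(kmax)
  npairs <- integer(kmax)
  for (m in seq_len(kmax)) {
    dx <- x[(m + 1):n] - x[1:(n - m)]
    dy <- y[(m + 1):n] - y[1:(n - m)]
    msd[m] <- mean(dx * dx + dy * dy)
    npairs[m] <- n - m
  }
  structure(
    list(lags = dt * seq_len(kmax), msd = msd, n_pairs = npairs, dt = dt),
    class = "msd_curve"
  )
}

#' Fit the random motility coefficient from an MSD curve
#'
#' The default `brownian_linear` model takes the weighted least-squares slope
#' of MSD against lag through the origin (weights = number of pair averages
#' per lag), restricted to the first quarter of the available lags where the
#' curve is best sampled, and returns `rmc = slope / 4` (2D diffusion).
#' The `prw` model fits Furth's persistent-random-walk form
#' `MSD(tau) = 4 D (tau - P (1 - exp(-tau / P)))` and returns `rmc = D`.
#' Negative estimates are floored at 0 and flagged.
#'
#' @param msd An [compute_msd()] result.
#' @param model `"brownian_linear"` or `"prw"`.
#' @param lag_fraction Fraction of lags used by the linear fit.
#' @return A `motility_fit` list with `rmc`, `slope_se`, `lags_used`,
#'   `floored` and `model`.
#' @export
fit_rmc <- function(msd, model = c("brownian_linear", "prw"),
                    lag_fraction = 0.25) {
  stopifnot(inherits(msd, "msd_curve"))
  model <- match.arg(model)
  k <- length(msd$lags)
  if (k < 2L) stop("at least 2 lags are required to fit the RMC")
  if (model == "brownian_linear") {
    nuse <- max(2L, as.integer(ceiling(lag_fraction * k)))
    tau <- msd$lags[seq_len(nuse)]
    y <- msd$msd[seq_len(nuse)]
    w <- as.numeric(msd$n_pairs[seq_len(nuse)])
    sxx <- sum(w * tau * tau)
    if (sxx <= 0) stop("singular MSD fit: degenerate lag design")
    slope <- sum(w * tau * y) / sxx
    resid <- y - slope * tau
    dof <- max(1L, nuse - 1L)
    slope_se <- sqrt(sum(w * resid^2) / dof / sxx)
    rmc <- slope / 4
    floored <- rmc < 0
    structure(
      list(rmc = max(0, rmc), slope_se = slope_se, lags_used = tau,
           floored = floored, model = model),
      class = "motility_fit"
    )
  } else {
    tau <- msd$lags
    y <- msd$msd
    d0 <- max(sum(y * tau) / sum(tau^2) / 4, 1e-8)
    obj <- function(par) {
      d <- exp(par[1]); p <- exp(par[2])
      sum((y - 4 * d * (tau - p * (1 - exp(-tau / p))))^2)
    }
    fit <- optim(c(log(d0), log(msd$dt)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    structure(
      list(rmc = exp(fit$par[1]), persistence_time = exp(fit$par[2]),
           slope_se = NA_real_, lags_used = tau, floored = FALSE,
           model = model),
      class = "motility_fit"
    )
  }
}

#' Tumor-level mean motility
#'
#' Pools per-cell RMC estimates across all gel-stiffness conditions and
#' returns their unweighted arithmetic mean, mirroring how a tumor's mean
#' motility is obtained from its cell ensemble. With `enforce_min_cells`,
#' subjects with any condition below `min_cells` tracked cells are flagged
#' as excluded (the cohort inclusion rule).
#'
#' @param estimates A data.frame with columns `rmc` and `stiffness_kpa`
#'   (one row per cell), or a bare numeric vector of per-cell RMCs.
#' @param enforce_min_cells Apply the per-condition cell-count rule.
#' @param min_cells Minimum cells per condition when enforcing.
#' @return A list with `tumor_mean` (um^2/min), `n_cells`, `excluded`,
#'   and `condition_counts`.
#' @examples
#' subject_mean_motility(data.frame(rmc = c(1, 2, 3), stiffness_kpa = 0.7))
#' @export
subject_mean_motility <- function(estimates, enforce_min_cells = FALSE,
                                  min_cells = 25) {
  if (is.numeric(estimates)) {
    estimates <- data.frame(rmc = estimates, stiffness_kpa = NA_real_)
  }
  if (!nrow(estimates)) stop("no cell motility estimates supplied")
  if (!all(is.finite(estimates$rmc))) stop("rmc values must be finite")
  counts <- table(estimates$stiffness_kpa)
  excluded <- FALSE
  if (enforce_min_cells && any(counts < min_cells)) {
    excluded <- TRUE
  }
  list(
    tumor_mean = mean(estimates$rmc),
    n_cells = nrow(estimates),
    excluded = excluded,
    condition_counts = counts
  )
}

#' Estimate motility for every cell and subject in a track table
#'
#' Runs [compute_msd()] and [fit_rmc()] for each cell and aggregates with
#' [subject_mean_motility()]. When all tracks of a subject share the same
#' uniform time grid the MSD/fit computation is vectorised across cells;
#' the result is identical to the per-track path.
#'
#' @param tracks A long-format track table as produced by
#'   [simulate_tracks()] or [read_tracks()].
#' @param model Passed to [fit_rmc()].
#' @param max_lag_fraction Passed to [compute_msd()].
#' @param lag_fraction Passed to [fit_rmc()].
#' @param enforce_min_cells,min_cells Passed to [subject_mean_motility()].
#' @return A list with `cells` (per-cell data.frame: `subject_id`,
#'   `cell_id`, `stiffness_kpa`, `rmc`, `floored`) and `subjects`
#'   (per-subject data.frame: `subject_id`, `tumor_mean`, `n_cells`,
#'   `excluded`).
#' @export
estimate_motility <- function(tracks, model = "brownian_linear",
                              max_lag_fraction = 1, lag_fraction = 0.25,
                              enforce_min_cells = FALSE, min_cells = 25) {
  need <- c("subject_id", "stiffness_kpa", "cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop("tracks must have columns ", paste(need, collapse = ", "))
  }
  key <- interaction(tracks$subject_id, tracks$stiffness_kpa,
                     tracks$cell_id, drop = TRUE)
  nt <- tabulate(key)
  uniform <- length(unique(nt)) == 1L && model == "brownian_linear"
  if (uniform) {
    ord <- order(key, tracks$t_min)
    n <- nt[1]
    ncell <- nlevels(key)
    x <- matrix(tracks$x_um[ord], nrow = n)
    y <- matrix(tracks$y_um[ord], nrow = n)
    t1 <- tracks$t_min[ord][seq_len(n)]
    dt <- t1[2] - t1[1]
    kmax <- max(1L, as.integer(floor(max_lag_fraction * (n - 1))))
    nuse <- max(2L, as.integer(ceiling(lag_fraction * kmax)))
    tau <- dt * seq_len(nuse)
    w <- as.numeric(n - seq_len(nuse))
    num <- numeric(ncell)
    den <- sum(w * tau * tau)
    for (m in seq_len(nuse)) {
      dx <- x[(m + 1):n, , drop = FALSE] - x[1:(n - m), , drop = FALSE]
      dy <- y[(m + 1):n, , drop = FALSE] - y[1:(n - m), , drop = FALSE]
      msd_m <- colMeans(dx * dx + dy * dy)
      num <- num + w[m] * tau[m] * msd_m
    }
    rmc <- num / den / 4
    first <- ord[seq(1, length(ord), by = n)]
    cells <- data.frame(
      subject_id = tracks$subject_id[first],
      cell_id = tracks$cell_id[first],
      stiffness_kpa = tracks$stiffness_kpa[first],
      rmc = pmax(0, rmc),
      floored = rmc < 0
    )
  } else {
    idx <- split(seq_len(nrow(tracks)), key)
    cells <- do.call(rbind, lapply(idx, function(ii) {
      tr <- tracks[ii, ]
      fit <- fit_rmc(msd_core(tr$t_min, tr$x_um, tr$y_um, max_lag_fraction),
                     model = model, lag_fraction = lag_fraction)
      data.frame(
        subject_id = tr$subject_id[1], cell_id = tr$cell_id[1],
        stiffness_kpa = tr$stiffness_kpa[1], rmc = fit$rmc,
        floored = fit$floored
      )
    }))
    rownames(cells) <- NULL
  }
  subjects <- do.call(rbind, lapply(
    split(cells, cells$subject_id),
    function(cc) {
      sm <- subject_mean_motility(cc, enforce_min_cells, min_cells)
      data.frame(
        subject_id = cc$subject_id[1], tumor_mean = sm$tumor_mean,
        n_cells = sm$n_cells, excluded = sm$excluded
      )
    }
  ))
  rownames(subjects) <- NULL
  list(cells = cells, subjects = subjects)
}
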