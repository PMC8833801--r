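#' Configuration for the cell-track simulator
#'
#' Describes one subject's in-vitro imaging experiment: cells plated on a set
#' of polyacrylamide gel stiffnesses and imaged every `dt` minutes for
#' `duration` minutes (defaults: 15-min frames over 16 h, i.e. 65 frames).
#' Motion is either a pure Brownian walk with random motility coefficient
#' `rmc_true` (population MSD(tau) = 4 * rmc_true * tau in 2D) or a
#' persistent random walk (PRW, Ornstein-Uhlenbeck velocity) whose long-lag
#' diffusivity `speed^2 * persistence_time / 2` must equal `rmc_true`.
#'
#' @param n_cells Cells per stiffness condition (default 32, giving ~192
#'   tracks per subject over the default six gels).
#' @param rmc_true True random motility coefficient, um^2/min.
#' @param dt Frame interval in minutes.
#' @param duration Total imaging time in minutes (>= 2 * dt).
#' @param mode `"brownian"` or `"prw"`.
#' @param speed,persistence_time PRW parameters (um/min, min). If only
#'   `persistence_time` is given, `speed` is derived from `rmc_true`.
#' @param stiffness_labels Gel stiffness labels in kPa.
#' @return A `track_sim_config` list.
#' @examples
#' cfg <- track_sim_config(n_cells = 4, rmc_true = 1)
#' @export
track_sim_config <- function(n_cells = 32, rmc_true = 1, dt = 15,
                             duration = 960, mode = c("brownian", "prw"),
                             speed = NULL, persistence_time = NULL,
                             stiffness_labels = c(0.7, 4.6, 9.3, 19.5, 100, 200)) {
  mode <- match.arg(mode)
  chk <- function(x, nm, min = NULL) {
    if (length(x) != 1L || !is.finite(x)) {
      stop(sprintf("field '%s' must be a single finite number", nm))
    }
    if (!is.null(min) && x < min) {
      stop(sprintf("field '%s' must be >= %s", nm, format(min)))
    }
  }
  chk(n_cells, "n_cells", 1)
  chk(rmc_true, "rmc_true", 0)
  chk(dt, "dt")
  if (dt <= 0) stop("field 'dt' must be > 0")
  chk(duration, "duration", 2 * dt)
  if (!length(stiffness_labels) || any(!is.finite(stiffness_labels))) {
    stop("field 'stiffness_labels' must be finite kPa values")
  }
  if (mode == "prw") {
    if (is.null(persistence_time)) {
      stop("field 'persistence_time' is required in prw mode")
    }
    chk(persistence_time, "persistence_time")
    if (persistence_time <= 0) stop("field 'persistence_time' must be > 0")
    if (is.null(speed)) {
      speed <- sqrt(2 * rmc_true / persistence_time)
    }
    chk(speed, "speed", 0)
    d_implied <- speed^2 * persistence_time / 2
    if (rmc_true > 0 &&
        abs(d_implied - rmc_true) > 1e-9 * max(rmc_true, d_implied)) {
      stop("field 'speed': speed^2 * persistence_time / 2 must equal rmc_true")
    }
  }
  structure(
    list(
      n_cells = as.integer(n_cells), rmc_true = rmc_true, dt = dt,
      duration = duration, mode = mode, speed = speed,
      persistence_time = persistence_time,
      stiffness_labels = as.numeric(stiffness_labels)
    ),
    class = "track_sim_config"
  )
}

#' Simulate cell migration tracks
#'
#' Generates one 2D track per cell per gel-stiffness condition, sampled at
#' `t = 0, dt, ..., duration`. In Brownian mode each per-axis step is an
#' independent Gaussian with variance `2 * rmc_true * dt`; in PRW mode the
#' velocity follows an exactly discretised Ornstein-Uhlenbeck process with
#' RMS speed `speed` and persistence time `persistence_time`, integrated with
#' step `dt`, so short lags are ballistic (MSD ~ speed^2 tau^2) and the
#' long-lag MSD slope approaches `4 * rmc_true`.
#'
#' @param cfg A [track_sim_config()].
#' @param seed Integer seed; the simulation is reproducible given `cfg` and
#'   `seed`.
#' @param subject_id Label written to the `subject_id` column.
#' @return A data.frame with columns `subject_id`, `stiffness_kpa`,
#'   `cell_id`, `t_min`, `x_um`, `y_um` (long format, one row per frame).
#' @examples
#' tr <- simulate_tracks(track_sim_config(n_cells = 2, rmc_true = 1), seed = 1)
#' @export
simulate_tracks <- function(cfg, seed = 1L, subject_id = "s1") {
  stopifnot(inherits(cfg, "track_sim_config"))
  set.seed(as.integer(seed))
  times <- seq(0, cfg$duration, by = cfg$dt)
  nt <- length(times)
  n_per_cond <- cfg$n_cells
  out <- vector("list", length(cfg$stiffness_labels))
  cell0 <- 0L
  for (g in seq_along(cfg$stiffness_labels)) {
    if (cfg$mode == "brownian") {
      sdstep <- sqrt(2 * cfg$rmc_true * cfg$dt)
      dx <- matrix(rnorm((nt - 1) * n_per_cond, sd = sdstep), nt - 1)
      dy <- matrix(rnorm((nt - 1) * n_per_cond, sd = sdstep), nt - 1)
      x <- rbind(0, apply(dx, 2, cumsum))
      y <- rbind(0, apply(dy, 2, cumsum))
    } else {
      s2 <- cfg$speed^2 / 2 # per-axis stationary velocity variance
      a <- exp(-cfg$dt / cfg$persistence_time)
      innov_sd <- sqrt(s2 * (1 - a^2))
      vx <- matrix(0, nt, n_per_cond)
      vy <- matrix(0, nt, n_per_cond)
      vx[1, ] <- rnorm(n_per_cond, sd = sqrt(s2))
      vy[1, ] <- rnorm(n_per_cond, sd = sqrt(s2))
      if (nt > 1) {
        for (k in 2:nt) {
          vx[k, ] <- a * vx[k - 1, ] + rnorm(n_per_cond, sd = innov_sd)
          vy[k, ] <- a * vy[k - 1, ] + rnorm(n_per_cond, sd = innov_sd)
        }
      }
      x <- apply(rbind(0, vx[-nt, , drop = FALSE] * cfg$dt), 2, cumsum)
      y <- apply(rbind(0, vy[-nt, , drop = FALSE] * cfg$dt), 2, cumsum)
    }
    out[[g]] <- data.frame(
      subject_id = subject_id,
      stiffness_kpa = cfg$stiffness_labels[g],
      cell_id = rep(cell0 + seq_len(n_per_cond), each = nt),
      t_min = rep(times, times = n_per_cond),
      x_um = as.vector(x),
      y_um = as.vector(y)
    )
    cell0 <- cell0 + n_per_cond
  }
  do.call(rbind, out)
}
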