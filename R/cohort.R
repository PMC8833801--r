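#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort (default 31
#' subjects) of tumor phantoms whose mean cellular motility is a linear
#' function of four planted image features plus Gaussian noise, calibrated
#' so that the planted linear model explains `target_r2` of the motility
#' variance and the cohort motility distribution has the stated mean and SD
#' (defaults 2.24 and 1.25 um^2/min). The default planted features are the
#' four intensity/run-length features the full pipeline is designed to
#' recover; the decoy list holds six correlated catalogue features that a
#' bootstrap forest typically ranks alongside them.
#'
#' @param n_subjects Cohort size (>= 3).
#' @param volume_shape Phantom dimensions in voxels.
#' @param voxel_spacing Voxel spacing in mm.
#' @param planted_features Four catalogue feature names carrying the signal.
#' @param planted_coefficients Standardised effect sizes (same length as
#'   `planted_features`). All-zero coefficients produce a null cohort whose
#'   motility is pure noise.
#' @param target_r2 Fraction of motility variance explained by the planted
#'   linear predictor, in (0, 1).
#' @param motility_mean,motility_sd Cohort motility mean and SD, um^2/min.
#' @param n_decoy_features Number of decoy candidates recorded (<= 6).
#' @param n_cells_per_condition Simulated tracks per gel condition.
#' @param seed Master seed for the cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 31,
                          volume_shape = c(64, 64, 64),
                          voxel_spacing = c(1, 1, 1),
                          planted_features = c(
                            "firstorder_10Percentile",
                            "firstorder_Minimum",
                            "glrlm_GrayLevelNonUniformity",
                            "glrlm_LongRunLowGrayLevelEmphasis"
                          ),
                          planted_coefficients = c(1, -1, 0.7, 0.7),
                          target_r2 = 0.60,
                          motility_mean = 2.24,
                          motility_sd = 1.25,
                          n_decoy_features = 6,
                          n_cells_per_condition = 32,
                          seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be at least 3")
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must be in (0, 1)")
  if (motility_sd <= 0) stop("motility_sd must be positive")
  if (!all(planted_features %in% feature_catalogue())) {
    bad <- setdiff(planted_features, feature_catalogue())
    stop("unknown planted features: ", paste(bad, collapse = ", "))
  }
  if (length(planted_coefficients) != length(planted_features)) {
    stop("planted_coefficients must match planted_features in length")
  }
  decoys <- c(
    "glszm_GrayLevelVariance", "glrlm_RunPercentage",
    "gldm_HighGrayLevelEmphasis", "glszm_ZoneEntropy",
    "glcm_JointAverage", "gldm_DependenceNonUniformity"
  )[seq_len(min(n_decoy_features, 6))]
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      volume_shape = as.integer(volume_shape),
      voxel_spacing = as.numeric(voxel_spacing),
      planted_features = planted_features,
      planted_coefficients = as.numeric(planted_coefficients),
      decoy_features = decoys,
      target_r2 = target_r2,
      motility_mean = motility_mean,
      motility_sd = motility_sd,
      n_cells_per_condition = as.integer(n_cells_per_condition),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort with planted feature-motility structure
#'
#' For each subject, draws phantom parameters, renders the tumor volume,
#' extracts the full 107-feature vector (with cohort histogram matching),
#' and composes the motility response: the planted features are
#' standardised over the cohort, combined with the planted coefficients,
#' rescaled so the signal variance is `target_r2 * motility_sd^2`, and
#' Gaussian noise with variance `Var(signal) * (1 / target_r2 - 1)` is
#' added before shifting to `motility_mean`. Motility is clipped at 0.05
#' um^2/min (clipping is recorded; a warning is raised if more than 10% of
#' subjects clip). Cell tracks with `rmc_true` equal to each subject's
#' motility are simulated unless `include_tracks = FALSE`.
#'
#' @param cfg A [cohort_config()].
#' @param include_tracks Simulate per-subject cell tracks (slower).
#' @param keep_volumes Keep rendered volumes/masks in the result (memory
#'   heavy for large cohorts).
#' @return A `synthetic_cohort` list: `features` (n x 107 matrix),
#'   `motility`, `ground_truth` (data.frame with `mu` signal, `eps` noise,
#'   `clipped`), `tracks` (long data.frame or `NULL`), `subjects` (list of
#'   phantom params, plus volumes/masks when kept), `reference`, `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), include_tracks = TRUE,
                            keep_volumes = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  draw <- function(lo, hi) runif(n, lo, hi)
  # base radius scales with the grid so smaller phantoms stay proportioned
  # (0.14-0.235 of the smallest dimension = 9-15 voxels at the 64^3 default)
  par_tab <- data.frame(
    r0 = draw(0.140625, 0.234375) * min(cfg$volume_shape),
    ax = draw(0.8, 1.2), ay = draw(0.8, 1.2), az = draw(0.8, 1.2),
    rim_level = draw(850, 1150),
    core_frac = draw(0.15, 0.6),
    rim_sharp = draw(2, 6),
    texture_sd = draw(25, 90),
    corr_len = draw(1.2, 3.5),
    necro_frac = draw(0.05, 0.5)
  )
  subjects <- vector("list", n)
  volumes <- vector("list", n)
  masks <- vector("list", n)
  for (s in seq_len(n)) {
    p <- tumor_params(
      shape = cfg$volume_shape, spacing = cfg$voxel_spacing,
      radii = par_tab$r0[s] * c(par_tab$ax[s], par_tab$ay[s], par_tab$az[s]),
      rim_level = par_tab$rim_level[s], core_frac = par_tab$core_frac[s],
      rim_sharp = par_tab$rim_sharp[s], texture_sd = par_tab$texture_sd[s],
      corr_len = par_tab$corr_len[s], necro_frac = par_tab$necro_frac[s]
    )
    vm <- generate_tumor_volume(p, seed = sub_seeds[s])
    subjects[[s]] <- list(subject_id = sprintf("s%02d", s), params = p)
    volumes[[s]] <- vm$image
    masks[[s]] <- vm$mask
  }
  reference <- build_cohort_reference(volumes)
  feats <- t(vapply(
    seq_len(n),
    function(s) extract_all_features(volumes[[s]], masks[[s]], reference),
    numeric(length(feature_catalogue()))
  ))
  rownames(feats) <- vapply(subjects, `[[`, "", "subject_id")

  # plant the linear signal on cohort-standardised features
  set.seed(sub_seeds[n + 1L])
  z <- scale(feats[, cfg$planted_features, drop = FALSE])
  beta <- cfg$planted_coefficients
  mu_raw <- as.vector(z %*% beta)
  if (all(beta == 0)) {
    mu <- rep(0, n)
    eps <- rnorm(n, sd = cfg$motility_sd)
  } else {
    if (sd(mu_raw) == 0) stop("planted signal is degenerate (zero variance)")
    mu <- mu_raw * sqrt(cfg$target_r2) * cfg$motility_sd / sd(mu_raw)
    eps <- rnorm(n, sd = sqrt(var(mu) * (1 / cfg$target_r2 - 1)))
  }
  motility <- cfg$motility_mean + mu + eps
  clipped <- motility < 0.05
  motility[clipped] <- 0.05
  if (mean(clipped) > 0.10) {
    warning(sprintf("%d of %d subjects clipped at 0.05 um^2/min",
                    sum(clipped), n))
  }
  ground_truth <- data.frame(
    subject_id = rownames(feats), mu = mu, eps = eps,
    motility = motility, clipped = clipped
  )

  tracks <- NULL
  if (include_tracks) {
    tracks <- do.call(rbind, lapply(seq_len(n), function(s) {
      tc <- track_sim_config(
        n_cells = cfg$n_cells_per_condition, rmc_true = motility[s]
      )
      simulate_tracks(tc, seed = sub_seeds[s] + 1L,
                      subject_id = subjects[[s]]$subject_id)
    }))
  }
  if (keep_volumes) {
    for (s in seq_len(n)) {
      subjects[[s]]$image <- volumes[[s]]
      subjects[[s]]$mask <- masks[[s]]
    }
  }
  structure(
    list(
      features = feats, motility = motility, ground_truth = ground_truth,
      tracks = tracks, subjects = subjects, reference = reference,
      config = cfg, planted_coefficients = beta
    ),
    class = "synthetic_cohort"
  )
}
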