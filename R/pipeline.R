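#' Read a subject's image volume and segmentation mask from NIfTI
#'
#' Validates that both files load, share the same grid, carry positive
#' voxel spacing, and that the mask is binary and non-empty.
#'
#' @param image_path,mask_path Paths to NIfTI-1 files (.nii or .nii.gz).
#' @return A list with `image` ([image_volume()]) and `mask`
#'   ([segmentation_mask()]).
#' @export
read_subject <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("image voxel spacing must be positive: ", image_path)
  }
  ia <- as.array(img)
  ma <- as.array(msk)
  if (!identical(dim(ia), dim(ma))) {
    stop(sprintf("mask not aligned with image: %s vs %s",
                 paste(dim(ia), collapse = "x"),
                 paste(dim(ma), collapse = "x")))
  }
  vals <- unique(as.vector(ma))
  if (!all(vals %in% c(0, 1))) {
    stop("mask must be binary (0/1): ", mask_path)
  }
  list(
    image = image_volume(ia, sp),
    mask = segmentation_mask(ma > 0, sp)
  )
}

#' Write an image volume or mask as NIfTI-1
#'
#' @param volume An [image_volume()] or [segmentation_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- if (inherits(volume, "segmentation_mask")) {
    array(as.numeric(volume$data), dim(volume$data))
  } else {
    as_volume_array(volume)
  }
  sp <- volume_spacing(volume)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- sp
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a cell-track table from CSV
#'
#' Expects columns `subject_id`, `stiffness_kpa`, `cell_id`, `t_min`,
#' `x_um`, `y_um`; every cell must have at least 3 frames at uniform
#' spacing.
#'
#' @param path CSV path.
#' @return A validated track data.frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "stiffness_kpa", "cell_id", "t_min", "x_um", "y_um")
  missing <- setdiff(need, names(tr))
  if (length(missing)) {
    stop("track CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  key <- interaction(tr$subject_id, tr$stiffness_kpa, tr$cell_id,
                     drop = TRUE)
  for (ii in split(seq_len(nrow(tr)), key)) {
    tt <- sort(tr$t_min[ii])
    cid <- tr$cell_id[ii[1]]
    if (length(tt) < 3) {
      stop(sprintf("cell %s: tracks need at least 3 frames", cid))
    }
    dts <- diff(tt)
    if (any(dts <= 0) || any(abs(dts - dts[1]) > 1e-6 * dts[1])) {
      stop(sprintf("cell %s: non-uniform track timestamps", cid))
    }
  }
  tr
}

#' Configuration for an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort) or `"user-data"` (read
#'   NIfTI volumes/masks and a track CSV).
#' @param output_dir Directory for all written artifacts.
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param image_paths,mask_paths,tracks_path Input files (user-data mode);
#'   images and masks are parallel vectors, one per subject.
#' @param subject_ids Subject labels (user-data mode; defaults to file
#'   stems).
#' @param n_perm Permutations for the significance test.
#' @param k,n_trees,n_repeats,criterion Modelling settings.
#' @param seed Master seed fanned out to every stage.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "user-data"),
                       output_dir = tempfile("motiliomics_run_"),
                       cohort = cohort_config(),
                       image_paths = NULL, mask_paths = NULL,
                       tracks_path = NULL, subject_ids = NULL,
                       n_perm = 500, k = 10, n_trees = 100, n_repeats = 10,
                       criterion = "aicc", seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "user-data") {
    if (is.null(image_paths) || is.null(mask_paths) || is.null(tracks_path)) {
      stop("user-data mode requires image_paths, mask_paths and tracks_path")
    }
    if (length(image_paths) != length(mask_paths)) {
      stop("image_paths and mask_paths must be parallel vectors")
    }
    for (p in c(image_paths, mask_paths, tracks_path)) {
      if (!file.exists(p)) stop("file not found: ", p)
    }
    if (is.null(subject_ids)) {
      subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
    }
  }
  structure(
    list(mode = mode, output_dir = output_dir, cohort = cohort,
         image_paths = image_paths, mask_paths = mask_paths,
         tracks_path = tracks_path, subject_ids = subject_ids,
         n_perm = n_perm, k = k, n_trees = n_trees, n_repeats = n_repeats,
         criterion = criterion, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline and write a reproducibility report
#'
#' Executes the complete analysis: cohort generation (or NIfTI/CSV
#' ingestion), per-cell motility estimation, 107-feature extraction with
#' cohort histogram matching, full-data model fit, LOOCV with in-fold
#' selection, baseline comparison, and the permutation test. Writes
#' `features.csv`, `motility.csv`, `model.json`, `results.json` and
#' `report.md` (all stamped with the master seed and a config hash) to the
#' configured output directory.
#'
#' @param config A [run_config()].
#' @return A list with all stage results (`features`, `motility`, `fit`,
#'   `cv`, `perm`, `paths`), invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4)

  if (config$mode == "synthetic") {
    cohort <- stage("cohort", {
      cfg <- config$cohort
      cfg$seed <- stage_seeds[1]
      generate_cohort(cfg, include_tracks = TRUE)
    })
    tracks <- cohort$tracks
    feats <- cohort$features
  } else {
    tracks <- stage("read_tracks", read_tracks(config$tracks_path))
    subj <- stage("read_subjects", {
      lapply(seq_along(config$image_paths), function(s) {
        tryCatch(
          read_subject(config$image_paths[s], config$mask_paths[s]),
          error = function(e) {
            stop(sprintf("subject %s: %s", config$subject_ids[s],
                         conditionMessage(e)), call. = FALSE)
          }
        )
      })
    })
    feats <- stage("features", {
      reference <- build_cohort_reference(lapply(subj, `[[`, "image"))
      out <- t(vapply(
        subj,
        function(sb) extract_all_features(sb$image, sb$mask, reference),
        numeric(length(feature_catalogue()))
      ))
      rownames(out) <- config$subject_ids
      out
    })
  }

  mot <- stage("motility", estimate_motility(tracks))
  y_tab <- mot$subjects[match(rownames(feats), mot$subjects$subject_id), ]
  if (anyNA(y_tab$tumor_mean)) {
    stop("pipeline stage 'motility' failed: tracks missing for subjects ",
         paste(rownames(feats)[is.na(y_tab$tumor_mean)], collapse = ", "))
  }
  y <- y_tab$tumor_mean

  fit <- stage("model", fit_motility_model(
    feats, y, k = config$k, n_trees = config$n_trees,
    n_repeats = config$n_repeats, criterion = config$criterion,
    seed = stage_seeds[2]
  ))
  cv <- stage("loocv", loocv_evaluate(
    feats, y, k = config$k, n_trees = config$n_trees,
    n_repeats = config$n_repeats, criterion = config$criterion,
    seed = stage_seeds[3]
  ))
  perm <- stage("permutation", permutation_test(
    feats, y, n_perm = config$n_perm, seed = stage_seeds[4], k = config$k,
    n_trees = config$n_trees, n_repeats = config$n_repeats,
    criterion = config$criterion
  ))

  hash <- config_hash(config[c("mode", "n_perm", "k", "n_trees",
                               "n_repeats", "criterion", "seed")])
  meta <- list(seed = config$seed, config_hash = hash)
  paths <- list(
    features = file.path(config$output_dir, "features.csv"),
    motility = file.path(config$output_dir, "motility.csv"),
    model = file.path(config$output_dir, "model.json"),
    results = file.path(config$output_dir, "results.json"),
    report = file.path(config$output_dir, "report.md")
  )
  fdf <- data.frame(subject_id = rownames(feats), feats,
                    check.names = FALSE)
  fdf$seed <- config$seed
  fdf$config_hash <- hash
  write.csv(fdf, paths$features, row.names = FALSE)
  mdf <- mot$subjects
  mdf$seed <- config$seed
  mdf$config_hash <- hash
  write.csv(mdf, paths$motility, row.names = FALSE)
  model_json <- list(
    meta = meta,
    intercept = fit$model$intercept,
    coefficients = as.list(fit$model$coefficients),
    weights = as.list(fit$model$weights),
    gamma = fit$model$gamma,
    lambda = fit$model$lambda,
    standardization = fit$model$standardization,
    selected = fit$selected
  )
  writeLines(jsonlite::toJSON(model_json, auto_unbox = TRUE, digits = NA),
             paths$model)
  results <- list(
    meta = meta,
    n_subjects = nrow(feats),
    n_features = ncol(feats),
    in_sample = list(r2 = fit$r2, rmse = fit$rmse),
    loocv = list(rmse = cv$loocv_rmse, baseline_rmse = cv$baseline_rmse,
                 r2_fitted_line = cv$r2_fitted_line, n_folds = cv$n_folds),
    permutation = list(n_perm = perm$n_perm, p_r2 = perm$p_r2,
                       p_rmse = perm$p_rmse,
                       observed_r2 = perm$observed_r2,
                       observed_rmse = perm$observed_rmse)
  )
  writeLines(jsonlite::toJSON(results, auto_unbox = TRUE, digits = NA),
             paths$results)
  report <- c(
    "# motiliomics run report",
    "",
    sprintf("- mode: %s", config$mode),
    sprintf("- master seed: %d", config$seed),
    sprintf("- config hash: %s", hash),
    sprintf("- subjects: %d", nrow(feats)),
    sprintf("- feature columns: %d", ncol(feats)),
    "",
    "## Model",
    sprintf("- in-sample fitted-line R2: %.4f", fit$r2),
    sprintf("- in-sample RMSE: %.4f um^2/min", fit$rmse),
    sprintf("- retained features: %s",
            paste(names(which(fit$model$coefficients != 0)),
                  collapse = ", ")),
    "",
    "## LOOCV",
    sprintf("- folds: %d", cv$n_folds),
    sprintf("- LOOCV RMSE: %.4f um^2/min", cv$loocv_rmse),
    sprintf("- baseline (mean predictor) RMSE: %.4f um^2/min",
            cv$baseline_rmse),
    "",
    "## Permutation test",
    sprintf("- permutations: %d", perm$n_perm),
    sprintf("- p(R2): %.5f, p(RMSE): %.5f", perm$p_r2, perm$p_rmse)
  )
  writeLines(report, paths$report)
  invisible(list(features = feats, motility = mot, fit = fit, cv = cv,
                 perm = perm, paths = paths, meta = meta))
}
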