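#' Build a cohort intensity reference for histogram matching
#'
#' Averages the empirical quantile functions of all cohort volumes on a fixed
#' 1001-point probability grid. The result represents the "mean image
#' histogram" that individual volumes are matched to.
#'
#' @param volumes A list of [image_volume()] objects or 3D arrays.
#' @return An `intensity_reference` list with `probs` and `quantiles`.
#' @export
build_cohort_reference <- function(volumes) {
  if (!length(volumes)) stop("cannot build a reference from an empty cohort")
  probs <- seq(0, 1, length.out = 1001L)
  qmat <- vapply(
    volumes,
    function(v) quantile(as.vector(as_volume_array(v)), probs = probs,
                         names = FALSE, type = 7),
    numeric(length(probs))
  )
  structure(list(probs = probs, quantiles = rowMeans(qmat)),
            class = "intensity_reference")
}

#' Histogram-match a volume to a cohort reference
#'
#' Applies the monotone remapping `v -> Qref(F(v))`, where `F` is the
#' volume's own empirical CDF (via its quantile function on the reference
#' probability grid) and `Qref` the cohort reference quantile function. Rank
#' order of voxels is preserved; a constant-intensity volume is returned
#' unchanged with a warning.
#'
#' @param volume An [image_volume()] or 3D array.
#' @param reference An `intensity_reference` from [build_cohort_reference()].
#' @return The matched volume, same class as the input.
#' @export
histogram_match <- function(volume, reference) {
  stopifnot(inherits(reference, "intensity_reference"))
  arr <- as_volume_array(volume)
  v <- as.vector(arr)
  if (max(v) == min(v)) {
    warning("constant-intensity volume: histogram matching skipped")
    return(volume)
  }
  qs <- quantile(v, probs = reference$probs, names = FALSE, type = 7)
  u <- approx(qs, reference$probs, xout = v, rule = 2, ties = max)$y
  out <- approx(reference$probs, reference$quantiles, xout = u, rule = 2,
                ties = "ordered")$y
  res <- array(out, dim = dim(arr))
  if (inherits(volume, "image_volume")) {
    image_volume(res, volume$spacing)
  } else {
    res
  }
}

n_bins_for <- function(rng, bin_width) {
  as.integer(ceiling(rng / bin_width - 1e-9))
}

#' Choose a discretisation bin width for the masked intensities
#'
#' Selects, from the candidate widths `range/k` for `k = 50..125`, the width
#' whose resulting bin count is closest to `target_bins` (default 87, the
#' midpoint of the 50-125 bin rule that stabilises texture features against
#' intensity-range variation). The choice is deterministic.
#'
#' @param volume An [image_volume()] or array.
#' @param mask A [segmentation_mask()] or logical array.
#' @param target_bins Desired bin count within \[50, 125\].
#' @return The bin width (intensity units), with attribute `n_bins`.
#' @export
choose_bin_width <- function(volume, mask, target_bins = 87L) {
  arr <- as_volume_array(volume)
  m <- as_mask_array(mask)
  check_aligned(arr, m)
  vals <- arr[m]
  rng <- max(vals) - min(vals)
  if (rng <= 0) stop("constant masked region: bin width is undefined")
  if (target_bins < 50 || target_bins > 125) {
    stop("target_bins must lie in [50, 125]")
  }
  ks <- 50:125
  k <- ks[which.min(abs(ks - target_bins))]
  width <- rng / k
  stopifnot(n_bins_for(rng, width) >= 50, n_bins_for(rng, width) <= 125)
  structure(width, n_bins = n_bins_for(rng, width))
}

#' Discretise masked intensities into integer gray levels
#'
#' Maps each masked voxel value to `floor((v - min) / bin_width) + 1`,
#' capping the maximum at the number of bins so levels span `1..n_bins`.
#' Voxels outside the mask are coded 0.
#'
#' @inheritParams choose_bin_width
#' @param bin_width Positive bin width in intensity units.
#' @return A `discretized_volume` list: `levels` (integer array, 0 outside
#'   the mask), `n_bins`, `bin_width`, `min_masked` and `spacing`.
#' @export
discretize <- function(volume, mask, bin_width) {
  arr <- as_volume_array(volume)
  m <- as_mask_array(mask)
  check_aligned(arr, m)
  bin_width <- as.numeric(bin_width)
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be a single positive number")
  }
  vals <- arr[m]
  lo <- min(vals)
  rng <- max(vals) - lo
  # an exactly divisible maximum lands in its own bin (floor + 1); for a
  # non-divisible range this equals the ceiling count
  nb <- as.integer(floor(rng / bin_width + 1e-9)) + 1L
  lev <- array(0L, dim = dim(arr))
  lev[m] <- pmin(as.integer(floor((vals - lo) / bin_width)) + 1L, nb)
  structure(
    list(levels = lev, n_bins = nb, bin_width = bin_width, min_masked = lo,
         spacing = volume_spacing(volume, mask)),
    class = "discretized_volume"
  )
}

#' Extract the full 107-feature radiomics vector
#'
#' Runs the standard chain on one subject: optional histogram matching to a
#' cohort reference, per-subject bin-width selection, discretisation, then
#' all seven feature families (shape, first-order, GLCM, GLRLM, GLSZM,
#' NGTDM, GLDM). Texture families are computed on the discretised masked
#' volume; GLCM and GLRLM are computed per 3D direction (13 angles) and
#' averaged.
#'
#' @param volume An [image_volume()] (or 3D array).
#' @param mask A [segmentation_mask()] (or logical array) aligned with
#'   `volume`.
#' @param reference Optional `intensity_reference` for histogram matching.
#' @param bin_width Optional fixed bin width; chosen per subject via
#'   [choose_bin_width()] when `NULL`.
#' @return Named numeric vector of length 107, ordered as
#'   [feature_catalogue()].
#' @export
extract_all_features <- function(volume, mask, reference = NULL,
                                 bin_width = NULL) {
  if (!inherits(volume, "image_volume")) volume <- image_volume(volume)
  if (!inherits(mask, "segmentation_mask")) {
    mask <- segmentation_mask(mask, volume$spacing)
  }
  check_aligned(volume, mask)
  if (!is.null(reference)) volume <- histogram_match(volume, reference)
  if (is.null(bin_width)) bin_width <- choose_bin_width(volume, mask)
  disc <- discretize(volume, mask, bin_width)
  run <- function(fam, fun, ...) {
    res <- tryCatch(fun(...), error = function(e) {
      stop(sprintf("feature family '%s' failed: %s", fam,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  }
  out <- c(
    run("shape", shape_features, mask),
    run("firstorder", first_order_features, volume, mask, disc),
    run("glcm", glcm_features, disc),
    run("glrlm", glrlm_features, disc),
    run("glszm", glszm_features, disc),
    run("ngtdm", ngtdm_features, disc),
    run("gldm", gldm_features, disc)
  )
  stopifnot(identical(names(out), feature_catalogue()))
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite features: ", paste(bad, collapse = ", "))
  }
  out
}
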