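#' Image volume and segmentation mask containers
#'
#' Lightweight containers pairing a 3D scalar intensity grid (or binary mask)
#' with its voxel spacing in millimetres. These are the in-memory currency of
#' the radiomics extractor; [read_subject()] builds them from NIfTI files.
#'
#' @param data A 3D numeric array (`image_volume`) or an array coercible to
#'   logical (`segmentation_mask`).
#' @param spacing Numeric length-3 voxel spacing in mm per axis.
#' @return An object of class `image_volume` or `segmentation_mask` with
#'   elements `data` and `spacing`.
#' @examples
#' vol <- image_volume(array(rnorm(27), c(3, 3, 3)))
#' msk <- segmentation_mask(array(TRUE, c(3, 3, 3)))
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image data must be a 3D array")
  if (!all(is.finite(data))) stop("image intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be three positive finite numbers")
  }
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @rdname image_volume
#' @export
segmentation_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain missing values")
  if (!any(data)) stop("mask must contain at least one foreground voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be three positive finite numbers")
  }
  structure(list(data = data, spacing = spacing), class = "segmentation_mask")
}

as_volume_array <- function(x) {
  if (inherits(x, "image_volume")) x$data else as.array(x)
}

as_mask_array <- function(x) {
  m <- if (inherits(x, "segmentation_mask")) x$data else as.array(x)
  storage.mode(m) <- "logical"
  m
}

check_aligned <- function(volume, mask) {
  dv <- dim(as_volume_array(volume))
  dm <- dim(as_mask_array(mask))
  if (!identical(dv, dm)) {
    stop(sprintf(
      "image and mask shapes differ: %s vs %s",
      paste(dv, collapse = "x"), paste(dm, collapse = "x")
    ))
  }
  invisible(TRUE)
}

volume_spacing <- function(volume, mask = NULL) {
  if (inherits(volume, c("image_volume", "segmentation_mask"))) {
    return(volume$spacing)
  }
  if (!is.null(mask) && inherits(mask, "segmentation_mask")) return(mask$spacing)
  c(1, 1, 1)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s voxels, spacing %s mm\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x")
  ))
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf(
    "<segmentation_mask> %s voxels, %d foreground, spacing %s mm\n",
    paste(dim(x$data), collapse = "x"), sum(x$data),
    paste(signif(x$spacing, 4), collapse = "x")
  ))
  invisible(x)
}
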