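#' Parameters for the synthetic tumor phantom
#'
#' Describes one enhancing-tumor phantom: an ellipsoidal mask whose interior
#' intensity follows a smooth radial profile (bright enhancing rim, dark
#' core) plus a Gaussian random texture field, embedded in brain-like
#' background. The parameters map deterministically onto the image features
#' the cohort generator plants: `core_frac` (core intensity as a fraction of
#' `rim_level`; smaller = deeper necrotic dip) drives the first-order
#' minimum, `rim_sharp` (radial exponent; larger = thinner rim, larger dark
#' volume fraction) the lower percentiles, and `texture_sd`/`corr_len` the
#' run/zone structure.
#'
#' @param shape Volume dimensions in voxels (each >= 16).
#' @param spacing Voxel spacing, mm.
#' @param radii Ellipsoid semi-axes in voxels.
#' @param center Ellipsoid centre (voxel coordinates); volume centre when
#'   `NULL`.
#' @param rim_level Peak rim intensity (arbitrary T1c-like units).
#' @param core_frac Core/rim intensity ratio in (0, 1].
#' @param rim_sharp Radial profile exponent (>= 0).
#' @param texture_sd Standard deviation of the intratumoral texture field.
#' @param corr_len Correlation length of the texture field, voxels.
#' @param bg_mean,bg_sd Brain-tissue background intensity mean and noise SD.
#' @param air_mean,air_sd Intensity mean and SD of the dark air/skull
#'   region outside the brain ellipsoid. Real head MRI volumes carry a
#'   large dark compartment; the tumor's dark voxels rank inside that
#'   distribution, which keeps cohort histogram matching from pinning the
#'   masked minimum to a single reference value.
#' @param necro_frac Intensity of a small necrotic nugget inside the core,
#'   as a fraction of the core intensity; 1 disables the extra dip. The
#'   nugget gives the image minimum a driver of its own, largely
#'   independent of the broad core that sets the low percentiles.
#' @param necro_radius_frac Nugget semi-axes as a fraction of the tumor
#'   radii.
#' @return A `tumor_params` list.
#' @export
tumor_params <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         radii = c(14, 12, 13), center = NULL,
                         rim_level = 1000, core_frac = 0.35, rim_sharp = 3,
                         texture_sd = 50, corr_len = 2, bg_mean = 350,
                         bg_sd = 25, air_mean = 30, air_sd = 40,
                         necro_frac = 1, necro_radius_frac = 0.3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("shape must be three dimensions of at least 16 voxels")
  }
  if (any(radii <= 0)) stop("radii must be positive")
  if (core_frac <= 0 || core_frac > 1) stop("core_frac must be in (0, 1]")
  if (texture_sd < 0) stop("texture_sd must be >= 0")
  if (necro_frac <= 0 || necro_frac > 1) stop("necro_frac must be in (0, 1]")
  if (is.null(center)) center <- (shape + 1) / 2
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         radii = as.numeric(radii), center = as.numeric(center),
         rim_level = rim_level, core_frac = core_frac,
         rim_sharp = rim_sharp, texture_sd = texture_sd,
         corr_len = corr_len, bg_mean = bg_mean, bg_sd = bg_sd,
         air_mean = air_mean, air_sd = air_sd, necro_frac = necro_frac,
         necro_radius_frac = necro_radius_frac),
    class = "tumor_params"
  )
}

# Smooth a white-noise array with a Gaussian kernel (periodic FFT
# convolution) and restandardise to zero mean, unit SD.
gaussian_field <- function(shape, corr_len) {
  noise <- array(rnorm(prod(shape)), dim = shape)
  if (corr_len <= 0) return(noise)
  axes <- lapply(shape, function(n) {
    d <- seq_len(n) - 1
    d <- pmin(d, n - d) # circular distance from origin
    exp(-d^2 / (2 * corr_len^2))
  })
  kern <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  dim(kern) <- shape
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(shape)
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic enhancing-tumor volume and mask
#'
#' Renders the phantom described by [tumor_params()]: ellipsoidal tumor with
#' a bright rim and dark core (`intensity = core + (rim - core) * rho ^
#' rim_sharp` at normalised radius `rho`), correlated Gaussian texture
#' inside the mask, and noisy brain-like background outside. Two calls with
#' the same parameters and seed are bit-identical.
#'
#' @param params A [tumor_params()] object.
#' @param seed Integer seed.
#' @return A list with `image` ([image_volume()]) and `mask`
#'   ([segmentation_mask()]).
#' @export
generate_tumor_volume <- function(params, seed = 1L) {
  stopifnot(inherits(params, "tumor_params"))
  set.seed(as.integer(seed))
  sh <- params$shape
  # draw all random fields first so parameter sweeps reuse the same noise
  tex <- gaussian_field(sh, params$corr_len)
  bg <- params$bg_mean + params$bg_sd * gaussian_field(sh, 1.2)
  air <- params$air_mean + params$air_sd * array(rnorm(prod(sh)), sh)

  ellipsoid <- function(center, radii) {
    ex <- (seq_len(sh[1]) - center[1]) / radii[1]
    ey <- (seq_len(sh[2]) - center[2]) / radii[2]
    ez <- (seq_len(sh[3]) - center[3]) / radii[3]
    outer(outer(ex^2, ey^2, `+`), ez^2, `+`)
  }
  rho2 <- ellipsoid(params$center, params$radii)
  mask <- rho2 <= 1
  if (!any(mask)) stop("tumor mask is empty: radii too small for the grid")
  rho <- sqrt(pmin(rho2, 1))
  core <- params$rim_level * params$core_frac
  profile <- core + (params$rim_level - core) * rho^params$rim_sharp
  # homogeneous necrosis: texture attenuated inside the nugget
  tex_scale <- array(params$texture_sd, sh)
  if (params$necro_frac < 1) {
    # small off-centre necrotic nugget, darker than the surrounding core
    off <- c(0.3, 0.2, -0.25) * params$radii
    nug <- ellipsoid(params$center + off,
                     params$necro_radius_frac * params$radii) <= 1
    profile[nug & mask] <- core * params$necro_frac
    tex_scale[nug & mask] <- 0.2 * params$texture_sd
  }
  brain <- ellipsoid((sh + 1) / 2, 0.42 * sh) <= 1
  img <- air
  img[brain] <- bg[brain]
  # bright vessel-like foci scattered through the brain keep the enhancing
  # rim from being the unique global maximum (which would let cohort
  # histogram matching pin the bright tail to a constant)
  for (v in seq_len(8)) {
    ctr <- (sh + 1) / 2 + runif(3, -0.3, 0.3) * sh
    ves <- ellipsoid(ctr, rep(runif(1, 1.5, 3), 3)) <= 1 & brain
    img[ves] <- runif(1, 900, 1400) + 30 * tex[ves]
  }
  img[mask] <- profile[mask] + tex_scale[mask] * tex[mask]
  list(
    image = image_volume(img, params$spacing),
    mask = segmentation_mask(mask, params$spacing)
  )
}
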