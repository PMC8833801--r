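# Texture families computed on a discretised masked volume. Matrices are
# accumulated in C++ (13-direction GLCM/GLRLM, 26-connected GLSZM zones,
# 26-neighbourhood NGTDM, alpha = 0 GLDM); feature formulas live here.
# GLCM and GLRLM features are computed per direction and averaged.

glcm_features_one <- function(pmat) {
  ng <- nrow(pmat)
  tot <- sum(pmat)
  p <- pmat / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p) # == colSums by symmetry
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  sig <- sqrt(sig2)
  # diagonal (difference) and cross-diagonal (sum) probabilities
  k_diff <- 0:(ng - 1)
  p_diff <- numeric(ng)
  pd <- rowsum(as.vector(p), as.vector(abs(i - j)))
  p_diff[as.integer(rownames(pd)) + 1] <- pd
  k_sum <- 2:(2 * ng)
  p_sum <- numeric(2 * ng - 1)
  ps <- rowsum(as.vector(p), as.vector(i + j))
  p_sum[as.integer(rownames(ps)) - 1] <- ps
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  hxy <- ent(p)
  pxy <- outer(px, px)
  pos <- p > 0 & pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- ent(pxy)
  hx <- ent(px)
  da <- sum(k_diff * p_diff)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  # MCC: sqrt of the second-largest eigenvalue magnitude of
  # Q(i, j) = sum_k p(i, k) p(j, k) / (px(i) py(k)); 1 for a flat region
  mcc <- if (sum(px > 0) < 2) 1 else {
    invpx <- ifelse(px > 0, 1 / px, 0)
    q <- (p * invpx) %*% (t(p) * invpx)
    evq <- sort(abs(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, evq[2]))
  }
  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = ent(p_sum),
    SumSquares = sig2
  )
}

#' Gray-level co-occurrence matrix features (24)
#'
#' Symmetric distance-1 co-occurrence over the 13 unique 3D directions;
#' each feature is computed per direction and averaged. Degenerate
#' single-gray-level regions return the documented limits (Correlation and
#' MCC 1, entropies and contrast 0) rather than NaN.
#'
#' @param disc A [discretize()] result.
#' @return Named numeric vector of 24 `glcm_*` features.
#' @export
glcm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  d <- dim(disc$levels)
  ng <- disc$n_bins
  counts <- cpp_glcm_counts(as.integer(disc$levels), d[1], d[2], d[3], ng)
  dim(counts) <- c(ng, ng, 13)
  acc <- NULL
  nd <- 0
  for (k in 1:13) {
    pm <- matrix(counts[, , k], nrow = ng)
    if (sum(pm) == 0) next # direction with no valid pairs
    f <- glcm_features_one(pm)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) stop("mask too small for any co-occurrence pairs")
  setNames(acc / nd, paste0("glcm_", names(acc)))
}

glrlm_features_one <- function(rmat, n_voxels) {
  i <- row(rmat); j <- col(rmat)
  nr <- sum(rmat)
  p <- rmat / nr
  ri <- rowSums(rmat) # runs per gray level
  rj <- colSums(rmat) # runs per length
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  pp <- p[p > 0]
  c(
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    HighGrayLevelRunEmphasis = sum(rmat * i^2) / nr,
    LongRunEmphasis = sum(rmat * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(rmat * i^2 * j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(rmat * j^2 / i^2) / nr,
    LowGrayLevelRunEmphasis = sum(rmat / i^2) / nr,
    RunEntropy = -sum(pp * log2(pp)),
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / n_voxels,
    RunVariance = sum((j - mu_j)^2 * p),
    ShortRunEmphasis = sum(rmat / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(rmat * i^2 / j^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(rmat / (i^2 * j^2)) / nr
  )
}

#' Gray-level run-length matrix features (16)
#'
#' Maximal same-level runs are enumerated along each of the 13 unique 3D
#' directions (runs break at mask boundaries); the 16 standard features are
#' computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 `glrlm_*` features.
#' @export
glrlm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  d <- dim(disc$levels)
  ng <- disc$n_bins
  counts <- cpp_glrlm_counts(as.integer(disc$levels), d[1], d[2], d[3], ng)
  lmax <- max(d)
  dim(counts) <- c(ng, lmax, 13)
  nvox <- sum(disc$levels > 0)
  acc <- NULL
  for (k in 1:13) {
    f <- glrlm_features_one(matrix(counts[, , k], nrow = ng), nvox)
    acc <- if (is.null(acc)) f else acc + f
  }
  setNames(acc / 13, paste0("glrlm_", names(acc)))
}

size_weighted_features <- function(i, s, n, n_voxels, prefix,
                                   feature_names) {
  # shared machinery for GLSZM (s = zone size) and GLDM (s = dependence)
  nz <- sum(n)
  p <- n / nz
  mu_i <- sum(i * p)
  mu_s <- sum(s * p)
  gl_tot <- tapply(n, i, sum)
  sz_tot <- tapply(n, s, sum)
  vals <- c(
    SmallEmphasis = sum(n / s^2) / nz,
    LargeEmphasis = sum(n * s^2) / nz,
    GrayLevelNonUniformity = sum(gl_tot^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gl_tot^2) / nz^2,
    SizeNonUniformity = sum(sz_tot^2) / nz,
    SizeNonUniformityNormalized = sum(sz_tot^2) / nz^2,
    Percentage = nz / n_voxels,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    SizeVariance = sum((s - mu_s)^2 * p),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(n / i^2) / nz,
    HighGrayLevelEmphasis = sum(n * i^2) / nz,
    SmallLowEmphasis = sum(n / (i^2 * s^2)) / nz,
    SmallHighEmphasis = sum(n * i^2 / s^2) / nz,
    LargeLowEmphasis = sum(n * s^2 / i^2) / nz,
    LargeHighEmphasis = sum(n * i^2 * s^2) / nz
  )
  setNames(as.numeric(vals[names(feature_names)]),
           paste0(prefix, "_", unname(feature_names)))
}

#' Gray-level size-zone matrix features (16)
#'
#' Zones are maximal 26-connected sets of equal gray level; the feature set
#' mirrors the run-length family with zone size in place of run length.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 `glszm_*` features.
#' @export
glszm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  d <- dim(disc$levels)
  zones <- cpp_glszm_zones(as.integer(disc$levels), d[1], d[2], d[3])
  tab <- table(level = zones[, 1], size = zones[, 2])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  i <- as.numeric(df$level)
  s <- as.numeric(df$size)
  n <- as.numeric(df$Freq)
  nvox <- sum(disc$levels > 0)
  size_weighted_features(
    i, s, n, nvox, "glszm",
    c(
      GrayLevelNonUniformity = "GrayLevelNonUniformity",
      GrayLevelNonUniformityNormalized = "GrayLevelNonUniformityNormalized",
      GrayLevelVariance = "GrayLevelVariance",
      HighGrayLevelEmphasis = "HighGrayLevelZoneEmphasis",
      LargeEmphasis = "LargeAreaEmphasis",
      LargeHighEmphasis = "LargeAreaHighGrayLevelEmphasis",
      LargeLowEmphasis = "LargeAreaLowGrayLevelEmphasis",
      LowGrayLevelEmphasis = "LowGrayLevelZoneEmphasis",
      SizeNonUniformity = "SizeZoneNonUniformity",
      SizeNonUniformityNormalized = "SizeZoneNonUniformityNormalized",
      SmallEmphasis = "SmallAreaEmphasis",
      SmallHighEmphasis = "SmallAreaHighGrayLevelEmphasis",
      SmallLowEmphasis = "SmallAreaLowGrayLevelEmphasis",
      Entropy = "ZoneEntropy",
      Percentage = "ZonePercentage",
      SizeVariance = "ZoneVariance"
    )
  )
}

#' Neighbouring gray-tone difference matrix features (5)
#'
#' For each gray level, accumulates the absolute difference between the
#' level and the mean level of the in-mask 26-neighbourhood. Degenerate
#' regions take the defined limits (a perfectly homogeneous region has
#' maximal coarseness, reported as 1e6, and zero contrast/busyness/
#' complexity/strength).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 `ngtdm_*` features.
#' @export
ngtdm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  d <- dim(disc$levels)
  ng <- disc$n_bins
  res <- cpp_ngtdm(as.integer(disc$levels), d[1], d[2], d[3], ng)
  nvp <- sum(res$n)
  present <- which(res$n > 0)
  i <- as.numeric(present)
  p <- res$n[present] / nvp
  s <- res$s[present]
  ngp <- length(present)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contr <- if (ngp > 1) {
    sum(outer(p, p) * outer(i, i, `-`)^2) / (ngp * (ngp - 1)) * sum(s) / nvp
  } else 0
  # sums below run over all ordered pairs of present levels
  busy_den <- sum(abs(outer(i * p, i * p, `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  cplx <- if (ngp > 1) {
    sum(abs(outer(i, i, `-`)) * outer(p * s, p * s, `+`) /
          outer(p, p, `+`)) / nvp
  } else 0
  strength <- if (sum(s) > 0 && ngp > 1) {
    sum(outer(p, p, `+`) * outer(i, i, `-`)^2) / sum(s)
  } else 0
  vals <- c(
    Busyness = busyness,
    Coarseness = coarseness,
    Complexity = cplx,
    Contrast = contr,
    Strength = strength
  )
  setNames(as.numeric(vals), paste0("ngtdm_", names(vals)))
}

#' Gray-level dependence matrix features (14)
#'
#' The dependence of a voxel is one plus the number of in-mask
#' 26-neighbours sharing its gray level (dependence threshold alpha = 0);
#' the feature set mirrors the size-zone family with dependence in place of
#' zone size (every masked voxel contributes one dependence observation).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 `gldm_*` features.
#' @export
gldm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  d <- dim(disc$levels)
  ng <- disc$n_bins
  counts <- cpp_gldm_counts(as.integer(disc$levels), d[1], d[2], d[3], ng)
  nz <- which(counts > 0, arr.ind = TRUE)
  i <- as.numeric(nz[, 1])
  s <- as.numeric(nz[, 2]) # dependence size
  n <- counts[nz]
  nvox <- sum(disc$levels > 0)
  size_weighted_features(
    i, s, n, nvox, "gldm",
    c(
      Entropy = "DependenceEntropy",
      SizeNonUniformity = "DependenceNonUniformity",
      SizeNonUniformityNormalized = "DependenceNonUniformityNormalized",
      SizeVariance = "DependenceVariance",
      GrayLevelNonUniformity = "GrayLevelNonUniformity",
      GrayLevelVariance = "GrayLevelVariance",
      HighGrayLevelEmphasis = "HighGrayLevelEmphasis",
      LargeEmphasis = "LargeDependenceEmphasis",
      LargeHighEmphasis = "LargeDependenceHighGrayLevelEmphasis",
      LargeLowEmphasis = "LargeDependenceLowGrayLevelEmphasis",
      LowGrayLevelEmphasis = "LowGrayLevelEmphasis",
      SmallEmphasis = "SmallDependenceEmphasis",
      SmallHighEmphasis = "SmallDependenceHighGrayLevelEmphasis",
      SmallLowEmphasis = "SmallDependenceLowGrayLevelEmphasis"
    )
  )
}
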