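# Independent brute-force oracles. Everything here is written with naive
# enumeration (explicit loops over voxel pairs, runs, zones, neighbourhoods)
# so that agreement with the package's C++/vectorised paths is a genuine
# cross-check, not a tautology.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
  c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1),
  c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

oracle_msd <- function(t, x, y, max_lag_fraction = 1) {
  n <- length(t)
  dt <- t[2] - t[1]
  kmax <- floor(max_lag_fraction * (n - 1))
  msd <- numeric(kmax)
  npairs <- integer(kmax)
  for (m in seq_len(kmax)) {
    acc <- 0
    cnt <- 0
    for (s in seq_len(n)) {
      e <- s + m
      if (e <= n) {
        acc <- acc + (x[e] - x[s])^2 + (y[e] - y[s])^2
        cnt <- cnt + 1
      }
    }
    msd[m] <- acc / cnt
    npairs[m] <- cnt
  }
  list(lags = dt * seq_len(kmax), msd = msd, n_pairs = npairs)
}

inside <- function(v, d) all(v >= 1) && all(v <= d)

# per-direction symmetric co-occurrence counts by explicit pair enumeration
oracle_glcm_counts <- function(lev, ng) {
  d <- dim(lev)
  out <- array(0, c(ng, ng, 13))
  for (k in 1:13) {
    dd <- DIRS13[k, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- lev[x, y, z]
      if (i == 0) next
      q <- c(x, y, z) + dd
      if (!inside(q, d)) next
      j <- lev[q[1], q[2], q[3]]
      if (j == 0) next
      out[i, j, k] <- out[i, j, k] + 1
      out[j, i, k] <- out[j, i, k] + 1
    }
  }
  out
}

oracle_glcm_features_one <- function(cnt) {
  ng <- nrow(cnt)
  p <- cnt / sum(cnt)
  px <- rowSums(p)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- 0
  for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  pd <- numeric(ng)
  ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  acc <- cpr <- csh <- ctend <- ctr <- idf <- idm <- idmn <- idn <- 0
  invvar <- je <- mp <- 0
  hxy1 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    acc <- acc + i * j * pij
    cpr <- cpr + (i + j - 2 * mu)^4 * pij
    csh <- csh + (i + j - 2 * mu)^3 * pij
    ctend <- ctend + (i + j - 2 * mu)^2 * pij
    ctr <- ctr + (i - j)^2 * pij
    idf <- idf + pij / (1 + abs(i - j))
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + (i - j)^2 / ng^2)
    idn <- idn + pij / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + pij / (i - j)^2
    je <- je + pij^2
    mp <- max(mp, pij)
    if (pij > 0 && px[i] * px[j] > 0) {
      hxy1 <- hxy1 - pij * log2(px[i] * px[j])
    }
  }
  hxy <- ent(p)
  hx <- ent(px)
  hxy2 <- ent(outer(px, px))
  da <- sum((0:(ng - 1)) * pd)
  dv <- sum(((0:(ng - 1)) - da)^2 * pd)
  corr <- if (sig2 > 0) (acc - mu^2) / sig2 else 1
  mcc <- if (sum(px > 0) < 2) 1 else {
    q <- matrix(0, ng, ng)
    for (i in 1:ng) for (j in 1:ng) {
      s <- 0
      for (k in 1:ng) {
        if (px[i] > 0 && px[k] > 0) s <- s + p[i, k] * p[j, k] / (px[i] * px[k])
      }
      q[i, j] <- s
    }
    evq <- sort(abs(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, evq[2]))
  }
  c(
    Autocorrelation = acc, ClusterProminence = cpr, ClusterShade = csh,
    ClusterTendency = ctend, Contrast = ctr, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = ent(pd),
    DifferenceVariance = dv, Id = idf, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = invvar, JointAverage = mu, JointEnergy = je,
    JointEntropy = hxy, MCC = mcc, MaximumProbability = mp,
    SumAverage = sum((2:(2 * ng)) * ps), SumEntropy = ent(ps),
    SumSquares = sig2
  )
}

oracle_glcm_features <- function(lev, ng) {
  cnts <- oracle_glcm_counts(lev, ng)
  acc <- NULL
  nd <- 0
  for (k in 1:13) {
    if (sum(cnts[, , k]) == 0) next
    f <- oracle_glcm_features_one(matrix(cnts[, , k], ng))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  setNames(acc / nd, paste0("glcm_", names(acc)))
}

# runs by walking each direction ray from every start voxel
oracle_glrlm_counts <- function(lev, ng) {
  d <- dim(lev)
  lmax <- max(d)
  out <- array(0, c(ng, lmax, 13))
  for (k in 1:13) {
    dd <- DIRS13[k, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      v <- c(x, y, z)
      i <- lev[x, y, z]
      if (i == 0) next
      prev <- v - dd
      if (inside(prev, d) && lev[prev[1], prev[2], prev[3]] == i) next
      len <- 1
      nxt <- v + dd
      while (inside(nxt, d) && lev[nxt[1], nxt[2], nxt[3]] == i) {
        len <- len + 1
        nxt <- nxt + dd
      }
      out[i, len, k] <- out[i, len, k] + 1
    }
  }
  out
}

oracle_glrlm_features <- function(lev, ng) {
  cnts <- oracle_glrlm_counts(lev, ng)
  nvox <- sum(lev > 0)
  lmax <- dim(cnts)[2]
  total <- NULL
  for (k in 1:13) {
    r <- matrix(cnts[, , k], ng)
    nr <- sum(r)
    gln <- glnn <- glv <- hgl <- lre <- lrh <- lrl <- lgl <- 0
    rln <- rlnn <- rv <- sre <- srh <- srl <- re <- 0
    ri <- rowSums(r)
    rj <- colSums(r)
    mui <- 0; muj <- 0
    for (i in 1:ng) for (j in 1:lmax) {
      mui <- mui + i * r[i, j] / nr
      muj <- muj + j * r[i, j] / nr
    }
    for (i in 1:ng) for (j in 1:lmax) {
      rv_ij <- r[i, j]
      if (rv_ij == 0) next
      p <- rv_ij / nr
      glv <- glv + (i - mui)^2 * p
      rv <- rv + (j - muj)^2 * p
      hgl <- hgl + rv_ij * i^2
      lgl <- lgl + rv_ij / i^2
      lre <- lre + rv_ij * j^2
      sre <- sre + rv_ij / j^2
      lrh <- lrh + rv_ij * i^2 * j^2
      lrl <- lrl + rv_ij * j^2 / i^2
      srh <- srh + rv_ij * i^2 / j^2
      srl <- srl + rv_ij / (i^2 * j^2)
      re <- re - p * log2(p)
    }
    f <- c(
      GrayLevelNonUniformity = sum(ri^2) / nr,
      GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
      GrayLevelVariance = glv,
      HighGrayLevelRunEmphasis = hgl / nr,
      LongRunEmphasis = lre / nr,
      LongRunHighGrayLevelEmphasis = lrh / nr,
      LongRunLowGrayLevelEmphasis = lrl / nr,
      LowGrayLevelRunEmphasis = lgl / nr,
      RunEntropy = re,
      RunLengthNonUniformity = sum(rj^2) / nr,
      RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
      RunPercentage = nr / nvox,
      RunVariance = rv,
      ShortRunEmphasis = sre / nr,
      ShortRunHighGrayLevelEmphasis = srh / nr,
      ShortRunLowGrayLevelEmphasis = srl / nr
    )
    total <- if (is.null(total)) f else total + f
  }
  setNames(total / 13, paste0("glrlm_", names(total)))
}

# zones by repeated region growing with 26-connectivity
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    i <- lev[x, y, z]
    frontier <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(frontier)) {
      v <- frontier[[length(frontier)]]
      frontier[[length(frontier)]] <- NULL
      size <- size + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- v + c(dx, dy, dz)
        if (inside(q, d) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == i) {
          seen[q[1], q[2], q[3]] <- TRUE
          frontier[[length(frontier) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(i, size)
  }
  do.call(rbind, zones)
}

oracle_size_family <- function(i, s, n, nvox) {
  nz <- sum(n)
  p <- n / nz
  mui <- sum(i * p)
  mus <- sum(s * p)
  gl <- tapply(n, i, sum)
  sz <- tapply(n, s, sum)
  list(
    small = sum(n / s^2) / nz, large = sum(n * s^2) / nz,
    gln = sum(gl^2) / nz, glnn = sum(gl^2) / nz^2,
    szn = sum(sz^2) / nz, sznn = sum(sz^2) / nz^2,
    pct = nz / nvox, glv = sum((i - mui)^2 * p),
    szv = sum((s - mus)^2 * p), ent = -sum(p * log2(p)),
    lgl = sum(n / i^2) / nz, hgl = sum(n * i^2) / nz,
    sl = sum(n / (i^2 * s^2)) / nz, sh = sum(n * i^2 / s^2) / nz,
    ll = sum(n * s^2 / i^2) / nz, lh = sum(n * i^2 * s^2) / nz
  )
}

oracle_glszm_features <- function(lev) {
  zs <- oracle_zones(lev)
  key <- paste(zs[, 1], zs[, 2])
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  f <- oracle_size_family(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
                          as.numeric(agg), sum(lev > 0))
  setNames(
    c(f$gln, f$glnn, f$glv, f$hgl, f$large, f$lh, f$ll, f$lgl, f$szn,
      f$sznn, f$small, f$sh, f$sl, f$ent, f$pct, f$szv),
    paste0("glszm_", c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"
    ))
  )
}

oracle_ngtdm_features <- function(lev, ng) {
  d <- dim(lev)
  nvec <- numeric(ng)
  svec <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lev[x, y, z]
    if (i == 0) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (inside(q, d) && lev[q[1], q[2], q[3]] > 0) {
        nb <- c(nb, lev[q[1], q[2], q[3]])
      }
    }
    nvec[i] <- nvec[i] + 1
    if (length(nb)) svec[i] <- svec[i] + abs(i - mean(nb))
  }
  nvp <- sum(nvec)
  pres <- which(nvec > 0)
  i <- pres
  p <- nvec[pres] / nvp
  s <- svec[pres]
  ngp <- length(pres)
  coars <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  ctr <- 0; busy_den <- 0; cplx <- 0; strg <- 0
  for (a in seq_len(ngp)) for (b in seq_len(ngp)) {
    ctr <- ctr + p[a] * p[b] * (i[a] - i[b])^2
    busy_den <- busy_den + abs(i[a] * p[a] - i[b] * p[b])
    cplx <- cplx + abs(i[a] - i[b]) * (p[a] * s[a] + p[b] * s[b]) /
      (p[a] + p[b])
    strg <- strg + (p[a] + p[b]) * (i[a] - i[b])^2
  }
  contrast <- if (ngp > 1) ctr / (ngp * (ngp - 1)) * sum(s) / nvp else 0
  setNames(
    c(
      if (busy_den > 0) sum(p * s) / busy_den else 0,
      coars,
      if (ngp > 1) cplx / nvp else 0,
      contrast,
      if (sum(s) > 0 && ngp > 1) strg / sum(s) else 0
    ),
    paste0("ngtdm_", c("Busyness", "Coarseness", "Complexity", "Contrast",
                       "Strength"))
  )
}

oracle_gldm_features <- function(lev) {
  d <- dim(lev)
  recs <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lev[x, y, z]
    if (i == 0) next
    dep <- 1
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (inside(q, d) && lev[q[1], q[2], q[3]] == i) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(i, dep)
  }
  m <- do.call(rbind, recs)
  key <- paste(m[, 1], m[, 2])
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  f <- oracle_size_family(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
                          as.numeric(agg), nrow(m))
  setNames(
    c(f$ent, f$szn, f$sznn, f$szv, f$gln, f$glv, f$hgl, f$large, f$lh,
      f$ll, f$lgl, f$small, f$sh, f$sl),
    paste0("gldm_", c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance",
      "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
      "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"
    ))
  )
}
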