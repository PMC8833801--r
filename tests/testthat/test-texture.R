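# helper: lift a 2D level matrix into a 1-slice 3D volume
lift3d <- function(mat) array(mat, c(nrow(mat), ncol(mat), 1))

test_that("hand-enumerated horizontal runs give the textbook GLRLM values", {
  # rows [[1,1,2],[2,2,3],[3,3,3]]; horizontal (dir (0,1,0) in array terms)
  img <- lift3d(rbind(c(1L, 1L, 2L), c(2L, 2L, 3L), c(3L, 3L, 3L)))
  d <- dim(img)
  counts <- motiliomics:::cpp_glrlm_counts(as.integer(img), d[1], d[2], d[3],
                                           3L)
  dim(counts) <- c(3, 3, 13)
  horiz <- counts[, , 2] # direction (0, 1, 0): along matrix rows
  # runs: (1,len2), (2,len1), (2,len2), (3,len1), (3,len3)
  want <- matrix(0, 3, 3)
  want[1, 2] <- 1; want[2, 1] <- 1; want[2, 2] <- 1; want[3, 1] <- 1
  want[3, 3] <- 1
  expect_equal(horiz, want)
  nr <- sum(horiz)
  expect_equal(nr, 5)
  gln <- sum(rowSums(horiz)^2) / nr
  expect_equal(gln, 1.8) # (1 + 4 + 4) / 5
  lrlgle <- sum(horiz * outer(1:3, 1:3, function(i, j) j^2 / i^2)) / nr
  expect_equal(lrlgle, (4 + 0.25 + 1 + 1 / 9 + 1) / 5, tolerance = 1e-12)
})

test_that("a constant 1D segment is a single run with the run identities", {
  n <- 7
  seg <- array(1L, c(n, 1, 1))
  d <- make_disc(seg, 1)
  f <- glrlm_features(d)
  # along the segment: one run of length n (GLN 1, LRLGLE n^2); the other
  # 12 directions see n runs of length 1 (GLN n, LRLGLE 1)
  counts <- motiliomics:::cpp_glrlm_counts(as.integer(seg), n, 1, 1, 1L)
  dim(counts) <- c(1, n, 13)
  axial <- counts[, , 1]
  expect_equal(axial[n], 1) # single run of length n
  expect_equal(sum(axial), 1)
  expect_equal(unname(f["glrlm_GrayLevelNonUniformity"]), (1 + 12 * n) / 13)
  expect_equal(unname(f["glrlm_LongRunLowGrayLevelEmphasis"]),
               (n^2 + 12) / 13)
})

test_that("a two-level checkerboard has hand-computable GLCM contrast", {
  mat <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  img <- lift3d(mat)
  d <- make_disc(img, 2)
  counts <- motiliomics:::cpp_glcm_counts(as.integer(img), 6, 6, 1, 2L)
  dim(counts) <- c(2, 2, 13)
  # axis-aligned in-plane directions alternate levels: contrast (i-j)^2 = 1
  for (k in 1:2) {
    p <- counts[, , k] / sum(counts[, , k])
    expect_equal(sum(p * outer(1:2, 1:2, `-`)^2), 1)
    expect_equal(sum(p), 1)
  }
  # in-plane diagonals connect equal levels: contrast 0
  p4 <- counts[, , 4] / sum(counts[, , 4])
  expect_equal(sum(p4 * outer(1:2, 1:2, `-`)^2), 0)
})

test_that("GLCM marginals are proper probabilities on random volumes", {
  lev <- rand_levels(c(6, 6, 6), 5, seed = 31)
  counts <- motiliomics:::cpp_glcm_counts(as.integer(lev), 6, 6, 6, 5L)
  dim(counts) <- c(5, 5, 13)
  for (k in 1:13) {
    p <- counts[, , k] / sum(counts[, , k])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p)) # symmetry
  }
})

test_that("constant regions take the documented degenerate limits", {
  lev <- array(1L, c(5, 5, 5))
  d <- make_disc(lev, 1)
  g <- glcm_features(d)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_Correlation"]), 1)
  expect_equal(unname(g["glcm_MCC"]), 1)
  expect_equal(unname(g["glcm_JointEntropy"]), 0)
  expect_true(all(is.finite(g)))
  n <- ngtdm_features(d)
  expect_equal(unname(n["ngtdm_Contrast"]), 0)
  expect_equal(unname(n["ngtdm_Coarseness"]), 1e6)
  z <- glszm_features(d)
  expect_equal(unname(z["glszm_ZoneEntropy"]), 0) # one zone, p = 1
  expect_equal(unname(z["glszm_GrayLevelNonUniformity"]), 1)
})

test_that("GLRLM normalisation: run counts sum to N_r in every direction", {
  lev <- rand_levels(c(5, 5, 5), 4, seed = 17, mask_frac = 0.8)
  counts <- motiliomics:::cpp_glrlm_counts(as.integer(lev), 5, 5, 5, 4L)
  dim(counts) <- c(4, 5, 13)
  ora <- oracle_glrlm_counts(lev, 4)
  for (k in 1:13) {
    expect_equal(matrix(counts[, , k], 4), matrix(ora[, , k], 4))
    # every masked voxel belongs to exactly one run per direction
    expect_equal(sum(counts[, , k] %*% (1:5)), sum(lev > 0))
  }
})

test_that("all texture families match brute-force enumeration (smoke)", {
  for (seed in 1:6) {
    lev <- rand_levels(c(5, 5, 5), 4, seed = seed,
                       mask_frac = if (seed %% 2) 1 else 0.75)
    d <- make_disc(lev, 4)
    expect_equal(glcm_features(d), oracle_glcm_features(lev, 4),
                 tolerance = 1e-10)
    expect_equal(glrlm_features(d), oracle_glrlm_features(lev, 4),
                 tolerance = 1e-10)
    expect_equal(glszm_features(d), oracle_glszm_features(lev),
                 tolerance = 1e-10)
    expect_equal(ngtdm_features(d), oracle_ngtdm_features(lev, 4),
                 tolerance = 1e-10)
    expect_equal(gldm_features(d), oracle_gldm_features(lev),
                 tolerance = 1e-10)
  }
})

test_that("extraction returns the frozen 107-name catalogue deterministically", {
  p <- tumor_params(shape = c(24, 24, 24), radii = c(7, 6, 6))
  vm <- generate_tumor_volume(p, seed = 9)
  f1 <- extract_all_features(vm$image, vm$mask)
  f2 <- extract_all_features(vm$image, vm$mask)
  expect_identical(f1, f2)
  expect_length(f1, 107)
  expect_identical(names(f1), feature_catalogue())
})

test_that("features are invariant under axis flips of image and mask", {
  p <- tumor_params(shape = c(24, 24, 24), radii = c(7, 6, 5))
  vm <- generate_tumor_volume(p, seed = 10)
  f1 <- extract_all_features(vm$image, vm$mask)
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  f2 <- extract_all_features(
    image_volume(flip(vm$image$data)),
    segmentation_mask(flip(vm$mask$data))
  )
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("first-order statistics ignore voxel arrangement entirely", {
  set.seed(20)
  v <- array(rnorm(512, 80, 10), c(8, 8, 8))
  m <- array(runif(512) < 0.6, c(8, 8, 8))
  perm <- sample(512)
  fo1 <- first_order_features(image_volume(v), segmentation_mask(m))
  fo2 <- first_order_features(
    image_volume(array(v[perm], c(8, 8, 8))),
    segmentation_mask(array(m[perm], c(8, 8, 8)))
  )
  expect_equal(fo1, fo2, tolerance = 1e-12)
})
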