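test_that("first-order features match direct formulas on masked values", {
  set.seed(11)
  v <- array(rnorm(512, 100, 25), c(8, 8, 8))
  m <- array(runif(512) < 0.7, c(8, 8, 8))
  vol <- image_volume(v, c(1, 2, 1.5))
  msk <- segmentation_mask(m, c(1, 2, 1.5))
  fo <- first_order_features(vol, msk)
  vals <- v[m]
  expect_equal(unname(fo["firstorder_Mean"]), mean(vals))
  expect_equal(unname(fo["firstorder_Median"]), median(vals))
  expect_equal(unname(fo["firstorder_Minimum"]), min(vals))
  expect_equal(unname(fo["firstorder_Maximum"]), max(vals))
  expect_equal(unname(fo["firstorder_Energy"]), sum(vals^2))
  expect_equal(unname(fo["firstorder_TotalEnergy"]), 3 * sum(vals^2))
  expect_equal(unname(fo["firstorder_Variance"]),
               mean((vals - mean(vals))^2))
  expect_equal(unname(fo["firstorder_RootMeanSquared"]),
               sqrt(mean(vals^2)))
  expect_equal(unname(fo["firstorder_MeanAbsoluteDeviation"]),
               mean(abs(vals - mean(vals))))
})

test_that("the 10th percentile uses linear interpolation", {
  # independent oracle: textbook type-7 interpolation computed by hand
  v <- array(0, c(100, 1, 1))
  v[] <- sample(1:100)
  m <- array(TRUE, c(100, 1, 1))
  fo <- first_order_features(image_volume(v), segmentation_mask(m))
  # sorted values 1..100: h = (n - 1) p + 1 = 10.9 -> 10 + 0.9 * (11 - 10)
  expect_equal(unname(fo["firstorder_10Percentile"]), 10.9)
  expect_equal(unname(fo["firstorder_90Percentile"]), 90.1)
  expect_equal(unname(fo["firstorder_InterquartileRange"]), 75.25 - 25.75)
})

test_that("constant regions give zero variance and unit uniformity", {
  v <- array(7, c(8, 8, 8))
  m <- array(TRUE, c(8, 8, 8))
  fo <- first_order_features(image_volume(v), segmentation_mask(m),
                             make_disc(array(1L, c(8, 8, 8))))
  expect_equal(unname(fo["firstorder_Variance"]), 0)
  expect_equal(unname(fo["firstorder_Uniformity"]), 1)
  expect_equal(unname(fo["firstorder_Entropy"]), 0)
  expect_equal(unname(fo["firstorder_Skewness"]), 0)
})

test_that("minimum and low percentile rise when a constant is added", {
  set.seed(12)
  v <- array(rnorm(512, 10, 3), c(8, 8, 8))
  m <- array(TRUE, c(8, 8, 8))
  base <- first_order_features(image_volume(v), segmentation_mask(m))
  up <- first_order_features(image_volume(v + 5), segmentation_mask(m))
  expect_gte(up["firstorder_Minimum"], base["firstorder_Minimum"])
  expect_gte(up["firstorder_10Percentile"], base["firstorder_10Percentile"])
  expect_equal(unname(up["firstorder_Minimum"] - base["firstorder_Minimum"]),
               5, tolerance = 1e-10)
})

test_that("a digitised ball is nearly spherical and volumetrically right", {
  mask <- segmentation_mask(ball_mask(n = 31, r = 10))
  sf <- shape_features(mask)
  expect_gte(sf["shape_Sphericity"], 0.97)
  expect_lte(sf["shape_Sphericity"], 1.0)
  true_v <- 4 / 3 * pi * 1000
  expect_equal(unname(sf["shape_MeshVolume"]), true_v, tolerance = 0.05)
  expect_equal(unname(sf["shape_Maximum3DDiameter"]), 20, tolerance = 0.1)
  # near-spherical: axes nearly equal
  expect_equal(unname(sf["shape_Elongation"]), 1, tolerance = 0.05)
})

test_that("axis-aligned boxes have accurate mesh volume and diameters", {
  box <- array(FALSE, c(20, 20, 20))
  box[5:14, 5:10, 5:8] <- TRUE # 10 x 6 x 4 voxels
  sf <- shape_features(segmentation_mask(box))
  expect_equal(unname(sf["shape_MeshVolume"]), 240, tolerance = 0.05)
  expect_equal(unname(sf["shape_VoxelVolume"]), 240)
  expect_equal(unname(sf["shape_Maximum3DDiameter"]),
               sqrt(9^2 + 5^2 + 3^2), tolerance = 1e-10)
  expect_equal(unname(sf["shape_Maximum2DDiameterSlice"]),
               sqrt(9^2 + 5^2), tolerance = 1e-10)
})

test_that("doubling the voxel spacing scales volumes by eight", {
  box <- array(FALSE, c(16, 16, 16))
  box[4:11, 4:9, 4:8] <- TRUE
  s1 <- shape_features(segmentation_mask(box, c(1, 1, 1)))
  s2 <- shape_features(segmentation_mask(box, c(2, 2, 2)))
  expect_equal(unname(s2["shape_MeshVolume"] / s1["shape_MeshVolume"]), 8,
               tolerance = 1e-10)
  expect_equal(unname(s2["shape_VoxelVolume"] / s1["shape_VoxelVolume"]), 8)
  expect_equal(unname(s2["shape_SurfaceArea"] / s1["shape_SurfaceArea"]), 4,
               tolerance = 1e-10)
})

test_that("a single-voxel mask reports degenerate axes with a flag", {
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  sf <- shape_features(segmentation_mask(sv))
  expect_true(attr(sf, "degenerate"))
  expect_equal(unname(sf["shape_MajorAxisLength"]), 0)
  expect_equal(unname(sf["shape_Elongation"]), 0)
  expect_gt(sf["shape_MeshVolume"], 0)
})
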