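test_that("NIfTI round-trip preserves data to float precision and the affine exactly", {
  set.seed(2)
  run <- BOLDRun(array(rnorm(6 * 5 * 4 * 8, 100, 10), c(6, 5, 4, 8)),
                 voxelSizeMm = 3)
  f <- tempfile(fileext = ".nii.gz")
  writeBOLDRun(run, f)
  back <- readBOLDRun(f, trSeconds = run@trSeconds)
  expect_equal(back@affine, run@affine)
  expect_lt(max(abs(back@data - run@data)) / max(abs(run@data)), 1e-6)

  m <- VoxelMask(array(runif(6 * 5 * 4) > 0.5, c(6, 5, 4)),
                 affine = run@affine)
  fm <- tempfile(fileext = ".nii.gz")
  writeVoxelMask(m, fm)
  expect_identical(readVoxelMask(fm)@data, m@data)
})

test_that("intensity mask keeps voxels above the robust-max fraction", {
  d <- array(100, c(6, 6, 4, 10))
  run <- BOLDRun(d)
  expect_true(all(intensityMask(run, 0.4)@data))

  # dropout block attenuated to 0.1 of baseline falls below 40%
  cfg <- tinyConfig(seed = 3)
  r <- generateRun(cfg, 1, "POST_OFF")
  m <- intensityMask(r, 0.4)
  expect_false(any(m@data[cfg@dropoutVoxels]))
  keep <- array(TRUE, dim(m@data)); keep[cfg@dropoutVoxels] <- FALSE
  expect_true(all(m@data[keep]))

  # near-empty mask is an error naming the fraction
  bright <- array(0, c(4, 4, 2, 5)); bright[2, 2, 1, ] <- 1000
  expect_error(intensityMask(BOLDRun(bright), 0.999), "0.999")
})

test_that("mask combination is an AND across grids", {
  a <- VoxelMask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)))
  b <- VoxelMask(array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1)))
  expect_identical(combineMasksAll(list(a, a))@data, a@data)
  comp <- VoxelMask(!a@data)
  expect_false(any(combineMasksAll(list(a, comp))@data))
  expect_identical(combineMasksAll(list(a, b))@data, a@data & b@data)
  expect_identical(maskConjunction(a, b)@data, a@data & b@data)
  set.seed(4)
  ms <- lapply(1:3, function(i) VoxelMask(array(runif(8) > 0.4, c(2, 2, 2))))
  expect_lte(sum(combineMasksAll(ms)@data),
             min(vapply(ms, function(m) sum(m@data), 1)))
  wrong <- VoxelMask(array(TRUE, c(3, 2, 1)))
  expect_error(combineMasksAll(list(a, wrong)), "grid mismatch")
})

test_that("Gaussian smoothing preserves constants and matches a dense convolution oracle", {
  const <- BOLDRun(array(7, c(6, 6, 6, 2)))
  sm <- gaussianSmooth(const, 8)
  expect_equal(sm@data, const@data, tolerance = 1e-12)

  # unit impulse, 8 mm FWHM, 3 mm voxels; kernel radius ceiling(5*sigma)=6
  # so a 13^3 grid holds the whole kernel without boundary effects
  d <- array(0, c(13, 13, 13, 2)); d[7, 7, 7, ] <- 1
  run <- BOLDRun(d, voxelSizeMm = 3)
  sm <- gaussianSmooth(run, 8)
  sigma <- (8 / (2 * sqrt(2 * log(2)))) / 3
  k <- dnorm(seq(-6, 6), sd = sigma); k <- k / sum(k)
  oracle <- outer(outer(k, k), k)       # dense separable convolution
  expect_equal(sm@data[7, 7, 7, 1], k[7]^3, tolerance = 1e-10)
  expect_equal(sm@data[, , , 1], oracle, tolerance = 1e-10)
  expect_equal(sum(sm@data[, , , 1]), 1, tolerance = 1e-6)  # mass preserved

  # semigroup: smoothing twice with f equals once with f*sqrt(2)
  # (discretized kernels satisfy this only approximately; at 8 mm FWHM on
  # 3 mm voxels the sampled-kernel error is ~1e-6 per axis)
  set.seed(5)
  r <- BOLDRun(array(rnorm(10 * 10 * 6 * 2), c(10, 10, 6, 2)),
               voxelSizeMm = 3)
  twice <- gaussianSmooth(gaussianSmooth(r, 8), 8)
  once <- gaussianSmooth(r, 8 * sqrt(2))
  expect_lt(max(abs(twice@data - once@data)), 1e-3)
})

test_that("extracted time series are standardized and reproduce Pearson correlations", {
  cfg <- tinyConfig(seed = 6)
  run <- generateRun(cfg, 1, "PRE_OFF")
  mask <- intensityMask(run, 0.4)
  ts <- extractTimeSeries(run, mask)
  expect_lt(max(abs(rowMeans(ts@values))), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(ts@values^2)) - 1)), 1e-12)

  # dot product of standardized rows equals cor() of raw courses
  d <- dim(run@data)
  raw <- matrix(run@data, prod(d[1:3]), d[4])
  i1 <- ecmap:::linearIndex(ts@voxelIndex[1, , drop = FALSE], d[1:3])
  i2 <- ecmap:::linearIndex(ts@voxelIndex[25, , drop = FALSE], d[1:3])
  expect_equal(sum(ts@values[1, ] * ts@values[25, ]),
               cor(raw[i1, ], raw[i2, ]), tolerance = 1e-10)

  # constant voxels are dropped and reported
  d2 <- run@data; d2[3, 3, 3, ] <- 42
  run2 <- BOLDRun(d2, affine = run@affine)
  ts2 <- extractTimeSeries(run2, VoxelMask(array(TRUE, d[1:3]),
                                           affine = run@affine))
  expect_true(any(apply(ts2@dropped, 1, function(v) all(v == c(3, 3, 3)))))
})

test_that("standardization is idempotent", {
  ts <- randomTs(12, 18, seed = 8)
  again <- timeSeriesMatrix(ts@values)
  expect_equal(again@values, ts@values, tolerance = 1e-12)
})

test_that("maps write back to volume space with NaN outside the mask", {
  cfg <- tinyConfig(seed = 14)
  run <- generateRun(cfg, 1, "PRE_OFF")
  ts <- extractTimeSeries(run, intensityMask(run, 0.4))
  e <- ecMap(ts)
  vol <- mapToVolume(e@values, e@voxelIndex, e@gridDim, fill = NaN)
  expect_equal(vol[cbind(e@voxelIndex)], e@values)
  expect_equal(sum(is.nan(vol)), prod(e@gridDim) - length(e@values))
  f <- tempfile(fileext = ".nii.gz")
  writeMapNifti(e, f)
  img <- RNifti::readNifti(f)
  expect_equal(as.numeric(img[cbind(e@voxelIndex)]), e@values,
               tolerance = 1e-6)
})
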