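mkStat <- function(q, t, vox, dm, aff = diag(c(3, 3, 3, 1))) {
  new("StatMap", t = t, z = t, p = q, q = q, dfError = 48L,
      contrast = "toy", voxelIndex = vox, gridDim = dm, affine = aff)
}

test_that("seeds are connected components of strictly significant voxels", {
  dm <- c(10L, 10L, 4L)
  vox <- as.matrix(expand.grid(1:10, 1:10, 1:4)); colnames(vox) <- NULL
  lin <- ecmap:::linearIndex(vox, dm)
  q <- rep(1, nrow(vox)); t <- rep(0, nrow(vox))
  expect_length(seedsFromStatMap(mkStat(q, t, vox, dm)), 0)

  blobA <- ecmap:::linearIndex(blockVoxels(2:3, 2:3, 2), dm)
  blobB <- ecmap:::linearIndex(blockVoxels(7:8, 7:8, 3), dm)
  q[lin %in% blobA] <- 0.01
  q[lin %in% blobB] <- 0.001
  t[lin %in% blobB] <- c(1, 4, 2, 3)
  seeds <- seedsFromStatMap(mkStat(q, t, vox, dm), 0.05)
  expect_length(seeds, 2)
  sizes <- vapply(seeds, function(s) sum(s@mask@data), 1)
  expect_setequal(sizes, c(4, 4))
  got <- sort(unlist(lapply(seeds, function(s) which(s@mask@data))))
  expect_equal(as.numeric(got), sort(as.numeric(c(blobA, blobB))))

  # boundary convention: q exactly at the threshold is excluded
  q2 <- rep(1, nrow(vox)); q2[5] <- 0.05
  expect_length(seedsFromStatMap(mkStat(q2, t, vox, dm), 0.05), 0)
})

test_that("seed time course is the unweighted voxel mean", {
  cfg <- tinyConfig(seed = 12)
  run <- generateRun(cfg, 1, "PRE_ON")
  dm <- dim(run@data)[1:3]
  m1 <- array(FALSE, dm); m1[2, 2, 2] <- TRUE
  one <- seedTimecourse(run, VoxelMask(m1, run@affine))
  expect_equal(one, run@data[2, 2, 2, ])

  m2 <- m1; m2[3, 2, 2] <- TRUE
  two <- seedTimecourse(run, VoxelMask(m2, run@affine))
  expect_equal(two, (run@data[2, 2, 2, ] + run@data[3, 2, 2, ]) / 2)

  expect_error(seedTimecourse(run, VoxelMask(array(FALSE, dm), run@affine)),
               "empty seed")
})

test_that("the mean course of a perfectly coherent seed correlates 1 with each member", {
  tc <- rnorm(30)
  M <- rbind(2 * tc + 1, 5 * tc - 3, 0.5 * tc)   # same signal, affine scaled
  mean_tc <- colMeans(M)
  for (i in 1:3) expect_equal(cor(mean_tc, M[i, ]), 1, tolerance = 1e-12)
})

test_that("correlation maps reproduce trivial correlations and the Fisher transform", {
  ts <- randomTs(15, 24, seed = 31)
  own <- ts@values[4, ]
  cm <- correlationMap(ts, own, fisher = FALSE)
  expect_equal(cm@values[4], 1, tolerance = 1e-10)

  # a course orthogonal to voxel 1 gives r = 0 there
  v1 <- ts@values[1, ]
  orth <- rnorm(24); orth <- orth - mean(orth)
  orth <- orth - sum(orth * v1) / sum(v1^2) * v1
  cm0 <- correlationMap(ts, orth, fisher = FALSE)
  expect_lt(abs(cm0@values[1]), 1e-12)

  # Fisher z is monotone: identical voxel ranking
  seed <- rnorm(24)
  r <- correlationMap(ts, seed, fisher = FALSE)@values
  z <- correlationMap(ts, seed, fisher = TRUE)@values
  expect_identical(order(r), order(z))
  expect_equal(z, atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)),
               tolerance = 1e-12)

  expect_error(correlationMap(ts, rep(1, 24)), "zero variance")
})

test_that("seed correlation recovers the raised hub coupling in synthetic data", {
  hits <- 0L
  nRep <- 8L
  for (i in seq_len(nRep)) {
    cfg <- tinyConfig(seed = 300 + i)
    runOn <- generateRun(cfg, 1, "POST_ON_left")
    runOff <- generateRun(cfg, 1, "PRE_ON")
    mask <- intensityMask(runOn, 0.4)
    seedMask <- array(FALSE, cfg@gridShape)
    seedMask[cfg@regionBlocks$motor] <- TRUE
    seed <- VoxelMask(seedMask, runOn@affine)
    rOn <- correlationMap(extractTimeSeries(runOn, mask),
                          seedTimecourse(runOn, seed), fisher = FALSE)
    rOff <- correlationMap(extractTimeSeries(runOff, mask),
                           seedTimecourse(runOff, seed), fisher = FALSE)
    thal <- ecmap:::linearIndex(cfg@regionBlocks$thalamus, cfg@gridShape)
    sel <- ecmap:::linearIndex(rOn@voxelIndex, cfg@gridShape) %in% thal
    hits <- hits + (mean(rOn@values[sel]) > mean(rOff@values[sel]))
  }
  expect_gte(hits / nRep, 0.95)
})
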