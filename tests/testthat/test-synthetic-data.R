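test_that("generation is deterministic and insensitive to added subjects", {
  cfg <- tinyConfig(seed = 1)
  r1 <- generateRun(cfg, 2, "POST_OFF")
  r2 <- generateRun(cfg, 2, "POST_OFF")
  expect_identical(r1@data, r2@data)

  # stable per-run streams: a config with more subjects reproduces the
  # earlier subjects' runs bit for bit
  cfgBig <- tinyConfig(seed = 1, nSubjects = 5L)
  r3 <- generateRun(cfgBig, 2, "POST_OFF")
  expect_identical(r1@data, r3@data)
})

test_that("zero deltas give identical truth coupling across conditions", {
  zero <- matrix(0, 3, 3, dimnames = list(names(tinyRegions()),
                                          names(tinyRegions())))
  cfg <- tinyConfig(deltas = list(POST_ON_left = zero))
  study <- generateStudy(cfg)
  for (cn in cfg@conditions)
    expect_equal(study@truth$coupling[[cn]], study@truth$coupling[[1]])
  expect_length(study@truth$modulatedRegions, 0)
})

test_that("snr = 0 leaves off-block voxel correlations centred at zero", {
  # Monte Carlo over 50 seeds: the mean absolute between-region correlation
  # matches the null sampling level ~ 1/sqrt(T) and shrinks with T
  offCor <- function(T, seed) {
    cfg <- tinyConfig(seed = seed, snr = 0, nTimepoints = T, dropout = FALSE)
    run <- generateRun(cfg, 1, "PRE_OFF")
    dmn <- dim(run@data)
    A <- matrix(run@data, prod(dmn[1:3]), dmn[4])
    i <- ecmap:::linearIndex(cfg@regionBlocks$motor[1:4, ], cfg@gridShape)
    j <- ecmap:::linearIndex(cfg@regionBlocks$thalamus[1:4, ], cfg@gridShape)
    R <- cor(t(A[i, ]), t(A[j, ]))
    c(absMean = mean(abs(R)), signedMean = mean(R))
  }
  r40 <- vapply(1:50, function(s) offCor(40L, s), numeric(2))
  # no systematic correlation: signed mean within 3 SE of zero
  se40 <- sd(r40["signedMean", ]) / sqrt(50)
  expect_lt(abs(mean(r40["signedMean", ])), 3 * se40)

  # |r| shrinks ~ 1/sqrt(T): quadrupling T halves the mean level
  r160 <- vapply(1:50, function(s) offCor(160L, s + 100), numeric(2))
  ratio <- mean(r160["absMean", ]) / mean(r40["absMean", ])
  expect_lt(abs(ratio - 0.5), 0.1)
  expect_lt(mean(r160["absMean", ]), 0.1)
})

test_that("empirical latent correlations converge to the configured coupling", {
  cfg <- tinyConfig(seed = 5, nTimepoints = 600L, snr = 50)
  run <- generateRun(cfg, 1, "POST_ON_left")
  dmn <- dim(run@data)
  A <- matrix(run@data, prod(dmn[1:3]), dmn[4])
  i <- ecmap:::linearIndex(cfg@regionBlocks$motor[1, , drop = FALSE],
                           cfg@gridShape)
  j <- ecmap:::linearIndex(cfg@regionBlocks$thalamus[1, , drop = FALSE],
                           cfg@gridShape)
  want <- ecmap:::effectiveCoupling(cfg, "POST_ON_left")["motor", "thalamus"]
  expect_equal(cor(A[i, ], A[j, ]), want, tolerance = 0.12)
})

test_that("non-positive-definite coupling is rejected naming the condition", {
  rn <- names(tinyRegions())
  bad <- ecmap:::couplingDelta(rn, list(c("motor", "thalamus")), 0.9)
  expect_error(tinyConfig(deltas = list(POST_ON_right = bad)),
               "POST_ON_right")
})

test_that("clinical table generator respects means, flooring and integer scoring", {
  exact <- generateClinicalTable(4, c(43.2, 14.4, 29.4, 13.6),
                                 subjectSd = 0, noiseSd = 0, rngSeed = 1)
  for (s in 1:4)
    expect_equal(unlist(exact[s, -1], use.names = FALSE), c(43, 14, 29, 14))

  big <- generateClinicalTable(200, c(5, 1, 3, 1), subjectSd = 6,
                               noiseSd = 6, rngSeed = 2)
  scores <- as.matrix(big[, -1])
  expect_true(all(scores >= 0))
  expect_true(all(scores == round(scores)))
})

test_that("the planted 2x2 interaction is detected with high power", {
  # cell means with a method-by-state interaction; 200 replicates
  hits <- 0L
  for (rep in 1:200) {
    tab <- generateClinicalTable(13, c(43, 14, 29, 14), subjectSd = 8,
                                 noiseSd = 4, rngSeed = 5000 + rep)
    res <- rmAnova2x2(tab)
    hits <- hits + (res$pInteraction < 0.05)
  }
  expect_gt(hits / 200, 0.8)
})

test_that("a full study carries one run per subject x condition with shared geometry", {
  cfg <- tinyConfig(seed = 9, nSubjects = 2L)
  study <- generateStudy(cfg)
  expect_length(study@runs, 2L * 5L)
  expect_identical(names(study@runs)[1], "sub01.PRE_OFF")
  dims <- unique(lapply(study@runs, function(r) dim(r@data)))
  expect_length(dims, 1L)
  expect_length(study@motion, 10L)
  expect_identical(nrow(study@clinical), 2L)
  expect_identical(study@truth$hubLabel, "motor")
  expect_identical(sort(study@truth$modulatedRegions),
                   c("motor", "thalamus"))
})
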