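std5 <- c("PRE_OFF", "PRE_ON", "POST_OFF", "POST_ON_left", "POST_ON_right")

test_that("the flexible-factorial design has the documented shape and rank", {
  d <- buildDesign(sprintf("s%02d", 1:13), std5)
  expect_identical(dim(d@design), c(65L, 18L))
  expect_identical(qr(d@design)$rank, 17L)

  d2 <- buildDesign(c("a", "b"), c("x", "y"))
  expect_identical(qr(d2@design)$rank, 3L)

  expect_error(buildDesign(c("a", "a"), c("x", "y")), "duplicate")
})

test_that("estimability is the sum-to-zero rule on condition weights", {
  d <- buildDesign(c("a", "b", "c"), std5)
  ok <- contrastSpec(c(PRE_ON = -1, POST_ON_left = 1))
  expect_true(isEstimable(d, ok))
  expect_error(contrastSpec(c(PRE_OFF = 1)), "sum to zero")
})

test_that("voxelwise GLM matches the normal-equations oracle and classical paired t", {
  set.seed(21)
  subjects <- sprintf("s%d", 1:8)
  design <- buildDesign(subjects, c("A", "B"))
  maps <- matrix(rnorm(20 * 16), 20, 16)
  fit <- fitGLM(maps, design)
  expect_identical(fit$dfError, 16L - 9L)
  cs <- contrastSpec(c(A = -1, B = 1))
  stat <- contrastTMap(fit, cs)

  # oracle 1: generic least squares via lm() per voxel
  X <- design@design
  for (v in c(1, 7, 20)) {
    lmfit <- lm(maps[v, ] ~ 0 + X)
    cvec <- c(-1, 1, rep(0, 8))
    beta <- coef(lmfit); beta[is.na(beta)] <- 0
    # lm drops an aliased column; compare fitted contrast via predictions
    condA <- X[, "A"] == 1
    est <- mean(fitted(lmfit)[!condA]) - mean(fitted(lmfit)[condA])
    sigma2 <- sum(residuals(lmfit)^2) / lmfit$df.residual
    expect_identical(lmfit$df.residual, fit$dfError)
    expect_equal(unname(est),
                 as.numeric(crossprod(ecmap:::expandContrast(cs, design),
                                      fit$coef[, v])),
                 tolerance = 1e-10)
  }

  # oracle 2: two-condition contrast t equals the classical paired t
  for (v in 1:20) {
    a <- maps[v, X[, "A"] == 1]
    b <- maps[v, X[, "B"] == 1]
    tt <- t.test(b, a, paired = TRUE)
    expect_equal(stat@t[v], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("exact-fit maps give zero residual variance and recover the planted contrast", {
  design <- buildDesign(c("a", "b", "c"), c("A", "B", "C"))
  X <- design@design
  beta0 <- c(2, 5, 1, 0.5, -0.5, 0)        # condition effects + subject offsets
  y <- as.numeric(X %*% beta0)
  maps <- rbind(y, y + 0)                   # 2 identical "voxels"
  fit <- fitGLM(maps, design)
  expect_equal(max(fit$residVar), 0, tolerance = 1e-20)
  est <- as.numeric(crossprod(
    ecmap:::expandContrast(contrastSpec(c(A = -1, B = 1)), design),
    fit$coef[, 1]))
  expect_equal(est, 3, tolerance = 1e-10)   # B - A = 5 - 2
})

test_that("contrast t-statistics are scale invariant and vanish for identical conditions", {
  set.seed(22)
  design <- buildDesign(sprintf("s%d", 1:6), c("A", "B", "C"))
  X <- design@design
  maps <- matrix(rnorm(10 * nrow(X)), 10)
  # force condition C identical to condition B within every subject
  for (s in 1:6) {
    rows <- which(X[, 3 + s] == 1)
    maps[, rows[X[rows, "C"] == 1]] <- maps[, rows[X[rows, "B"] == 1]]
  }
  fit <- fitGLM(maps, design)
  sBC <- contrastTMap(fit, contrastSpec(c(B = -1, C = 1)))
  expect_equal(max(abs(sBC@t)), 0, tolerance = 1e-10)
  s1 <- contrastTMap(fit, contrastSpec(c(A = -1, B = 1)))
  s2 <- contrastTMap(fit, contrastSpec(c(A = -2, B = 2)))
  expect_equal(s1@t, s2@t, tolerance = 1e-10)
})

test_that("t-to-z conversion matches the probit identity and survives large t", {
  expect_equal(tToZ(5.04, 48), 4.4927, tolerance = 1e-4)
  expect_equal(tToZ(0, 30), 0, tolerance = 1e-12)
  expect_equal(tToZ(-2, 30), -tToZ(2, 30), tolerance = 1e-10)
  big <- tToZ(60, 48)
  expect_true(is.finite(big) && big > 10)
})

test_that("the contrast battery enumerates eleven sum-to-zero contrasts", {
  bat <- contrastBattery()
  expect_length(bat, 11L)
  for (cs in bat) expect_lt(abs(sum(cs@weights)), 1e-12)
  wsum <- function(cs) {
    out <- structure(numeric(5), names = std5)
    out[names(cs@weights)] <- cs@weights
    out
  }
  expect_equal(wsum(bat$POST_ON_minus_PRE_ON),
               wsum(bat$POST_ON_left_minus_PRE_ON) +
                 wsum(bat$POST_ON_right_minus_PRE_ON))
})

test_that("Benjamini-Hochberg step-up matches hand computation and is monotone", {
  p <- c(0.001, 0.02, 0.03, 0.2)
  res <- fdrBH(p, 0.05)
  expect_equal(res$q, p.adjust(p, "BH"))
  expect_equal(res$q, c(0.004, 0.04, 0.04, 0.2))
  expect_identical(sum(res$reject), 3L)
  expect_identical(sum(fdrBH(rep(1, 10), 0.05)$reject), 0L)
  set.seed(23)
  pr <- runif(100)
  r1 <- fdrBH(pr, 0.01)$reject
  r5 <- fdrBH(pr, 0.05)$reject
  expect_true(all(r5[r1]))
})

test_that("cluster extraction finds components, sizes and spaced local maxima", {
  dm <- c(12L, 12L, 6L)
  aff <- diag(c(3, 3, 3, 1))
  vox <- as.matrix(expand.grid(1:12, 1:12, 1:6))
  colnames(vox) <- NULL
  tvals <- rep(0, nrow(vox))
  q <- rep(1, nrow(vox))
  lin <- ecmap:::linearIndex(vox, dm)
  blob1 <- ecmap:::linearIndex(blockVoxels(2:3, 2:3, 2), dm)       # 4 voxels
  blob2 <- ecmap:::linearIndex(blockVoxels(8:9, 8:10, 3:4), dm)    # 12 voxels
  single <- ecmap:::linearIndex(cbind(12L, 1L, 6L), dm)
  hot <- lin %in% c(blob1, blob2, single)
  q[hot] <- 0.01
  tvals[hot] <- 5
  tvals[lin %in% blob2] <- 5 + seq_len(12) / 10
  stat <- new("StatMap", t = tvals, z = tvals, p = q, q = q,
              dfError = 48L, contrast = "toy", voxelIndex = vox,
              gridDim = dm, affine = aff)
  tab <- extractClusters(stat, qLevel = 0.05)
  expect_identical(length(unique(tab$cluster)), 3L)
  expect_setequal(unique(tab$k), c(4L, 12L, 1L))
  # single-voxel cluster reports its mm coordinate ((12,1,6)-1)*3
  srow <- tab[tab$k == 1, ]
  expect_equal(unlist(srow[c("x", "y", "z")], use.names = FALSE),
               c(33, 0, 15))
  # local maxima pairwise > 8 mm apart, at most 3 per cluster
  for (cl in unique(tab$cluster)) {
    mx <- tab[tab$cluster == cl, ]
    expect_lte(nrow(mx), 3L)
    if (nrow(mx) > 1) {
      dmat <- as.matrix(dist(mx[, c("x", "y", "z")]))
      expect_true(all(dmat[upper.tri(dmat)] > 8))
    }
  }
  # the peak of blob2 is its maximum t
  expect_equal(max(tab$T), max(tvals))
  # empty input allowed
  expect_identical(nrow(extractClusters(stat, reject = rep(FALSE, nrow(vox)))),
                   0L)
})

test_that("the interaction contrast is exactly zero under a pure additive PRE->POST shift", {
  set.seed(24)
  design <- buildDesign(sprintf("s%d", 1:7), std5)
  X <- design@design
  V <- 30
  base <- matrix(rnorm(V * 7), V, 7)        # subject patterns
  shift <- rnorm(V)                          # microlesion-like PRE->POST shift
  maps <- matrix(0, V, nrow(X))
  for (r in seq_len(nrow(X))) {
    s <- which(X[r, 5 + seq_len(7)] == 1)
    post <- X[r, "POST_OFF"] + X[r, "POST_ON_left"] + X[r, "POST_ON_right"]
    maps[, r] <- base[, s] + post * shift
  }
  fit <- fitGLM(maps, design)
  bat <- contrastBattery()
  for (nm in c("interaction_left", "interaction_right", "interaction_weighted")) {
    st <- contrastTMap(fit, bat[[nm]])
    expect_lt(max(abs(st@t)), 1e-8)
  }
})
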