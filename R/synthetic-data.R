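#' Voxel block helper
#'
#' @param x,y,z integer index ranges.
#' @return integer matrix with one row per voxel and columns x, y, z.
#' @export
blockVoxels <- function(x, y, z) {
  g <- expand.grid(x = as.integer(x), y = as.integer(y), z = as.integer(z))
  as.matrix(g)
}

validateSyntheticConfig <- function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (object@nTimepoints < 20L) msg <- c(msg, "nTimepoints must be >= 20")
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be positive")
  if (object@ar1Phi < 0 || object@ar1Phi >= 1)
    msg <- c(msg, "ar1Phi must be in [0, 1)")
  if (object@dropoutFactor < 0 || object@dropoutFactor >= 1)
    msg <- c(msg, "dropoutFactor must be in [0, 1)")
  K <- length(object@regionBlocks)
  if (K > 0) {
    if (is.null(names(object@regionBlocks)) ||
        anyDuplicated(names(object@regionBlocks)))
      msg <- c(msg, "regionBlocks must be uniquely named")
    allVox <- do.call(rbind, object@regionBlocks)
    if (any(allVox < 1L) ||
        any(sweep(allVox, 2, object@gridShape, ">") ))
      msg <- c(msg, "region voxels outside the grid")
    lin <- linearIndex(allVox, object@gridShape)
    if (anyDuplicated(lin)) msg <- c(msg, "region blocks must be disjoint")
    if (!all(dim(object@baseCoupling) == c(K, K)))
      msg <- c(msg, "baseCoupling must be K x K")
    else {
      if (max(abs(object@baseCoupling - t(object@baseCoupling))) > 1e-12)
        msg <- c(msg, "baseCoupling must be symmetric")
      if (max(abs(diag(object@baseCoupling) - 1)) > 1e-12)
        msg <- c(msg, "baseCoupling must have unit diagonal")
    }
    if (!object@hubLabel %in% names(object@regionBlocks))
      msg <- c(msg, "hubLabel must name a region block")
    bad <- setdiff(names(object@couplingDeltas), object@conditions)
    if (length(bad))
      msg <- c(msg, paste("couplingDeltas for unknown conditions:",
                          paste(bad, collapse = ", ")))
    if (!length(msg)) {
      for (cond in object@conditions) {
        C <- effectiveCoupling(object, cond)
        ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
        if (!ok)
          msg <- c(msg, sprintf(
            "effective coupling matrix for condition '%s' is not positive definite",
            cond))
      }
    }
  }
  if (nrow(object@dropoutVoxels) > 0 &&
      (any(object@dropoutVoxels < 1L) ||
       any(sweep(object@dropoutVoxels, 2, object@gridShape, ">"))))
    msg <- c(msg, "dropout voxels outside the grid")
  if (length(msg)) msg else TRUE
}

# base coupling plus the condition's delta (zero when absent)
effectiveCoupling <- function(config, condition) {
  C <- config@baseCoupling
  d <- config@couplingDeltas[[condition]]
  if (!is.null(d)) C <- C + d
  C
}

# symmetric delta matrix touching the named region pairs
couplingDelta <- function(regions, pairs, delta) {
  K <- length(regions)
  D <- matrix(0, K, K, dimnames = list(regions, regions))
  for (p in pairs) D[p[1], p[2]] <- D[p[2], p[1]] <- delta
  D
}

#' Configure a synthetic BOLD study
#'
#' Builds a [SyntheticConfig-class].  The defaults define the package's
#' reference study: a 16 x 16 x 8 grid of 3 mm voxels, 200 volumes at
#' TR 3 s, 13 subjects, the five conditions PRE_OFF, PRE_ON, POST_OFF,
#' POST_ON_left, POST_ON_right; a bilateral "motor" hub block (the planted
#' hub, two disconnected patches mimicking left/right motor cortex) plus
#' thalamus-, cerebellum- and two background-like blocks; coupling raised
#' in both unilateral stimulation conditions between the hub and the
#' thalamus/cerebellum blocks (+0.45) and between thalamus and cerebellum
#' (+0.25), planting a cortico-thalamo-cerebellar connectivity increase;
#' AR(1) voxel noise (phi = 0.3, unit innovations) at SNR 3; and an
#' electrode-like dropout block attenuated to 0.1 of baseline intensity.
#'
#' @param gridShape,voxelSizeMm,nTimepoints,trSeconds acquisition geometry.
#' @param nSubjects,conditions study layout.
#' @param regionBlocks named list of voxel-index matrices (see
#'   [blockVoxels()]); NULL selects the default layout for the default grid.
#' @param baseCoupling K x K symmetric unit-diagonal latent coupling.
#' @param couplingDeltas named list (by condition) of additive symmetric
#'   coupling changes.
#' @param hubLabel planted hub region.
#' @param ar1Phi,snr,baseline noise and signal scaling.
#' @param dropoutVoxels,dropoutFactor electrode-like signal dropout.
#' @param rngSeed master seed; per-run streams are derived by stable
#'   hashing.
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(gridShape = c(16L, 16L, 8L), voxelSizeMm = 3,
                            nTimepoints = 200L, trSeconds = 3,
                            nSubjects = 13L,
                            conditions = c("PRE_OFF", "PRE_ON", "POST_OFF",
                                           "POST_ON_left", "POST_ON_right"),
                            regionBlocks = NULL, baseCoupling = NULL,
                            couplingDeltas = NULL, hubLabel = "motor",
                            ar1Phi = 0.3, snr = 3, baseline = 100,
                            dropoutVoxels = NULL, dropoutFactor = 0.1,
                            rngSeed = 42L) {
  if (is.null(regionBlocks)) {
    regionBlocks <- list(
      motor = rbind(blockVoxels(3:6, 3:6, 4:6),
                    blockVoxels(11:14, 3:6, 4:6)),
      thalamus = blockVoxels(7:10, 8:11, 4:6),
      cerebellum = blockVoxels(6:9, 12:15, 2:4),
      occipital = blockVoxels(12:14, 12:14, 5:7),
      prefrontal = blockVoxels(3:5, 12:14, 5:7))
  }
  K <- length(regionBlocks)
  rn <- names(regionBlocks)
  if (is.null(baseCoupling)) {
    stopifnot(identical(rn, c("motor", "thalamus", "cerebellum",
                              "occipital", "prefrontal")))
    baseCoupling <- matrix(0.15, K, K, dimnames = list(rn, rn))
    baseCoupling["motor", "thalamus"] <- baseCoupling["thalamus", "motor"] <- 0.30
    baseCoupling["motor", "cerebellum"] <- baseCoupling["cerebellum", "motor"] <- 0.25
    baseCoupling["motor", "occipital"] <- baseCoupling["occipital", "motor"] <- 0.25
    baseCoupling["motor", "prefrontal"] <- baseCoupling["prefrontal", "motor"] <- 0.25
    baseCoupling["thalamus", "cerebellum"] <- baseCoupling["cerebellum", "thalamus"] <- 0.20
    diag(baseCoupling) <- 1
  }
  if (is.null(couplingDeltas)) {
    d <- couplingDelta(rn, list(c("motor", "thalamus"),
                                c("motor", "cerebellum")), 0.45) +
         couplingDelta(rn, list(c("thalamus", "cerebellum")), 0.25)
    couplingDeltas <- list(POST_ON_left = d, POST_ON_right = d)
    couplingDeltas <- couplingDeltas[names(couplingDeltas) %in% conditions]
  }
  if (is.null(dropoutVoxels)) dropoutVoxels <- blockVoxels(8:9, 8:9, 7:8)
  new("SyntheticConfig",
      gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      nSubjects = as.integer(nSubjects), conditions = conditions,
      regionBlocks = regionBlocks, baseCoupling = baseCoupling,
      couplingDeltas = couplingDeltas, hubLabel = hubLabel,
      ar1Phi = ar1Phi, snr = snr, baseline = baseline,
      dropoutVoxels = dropoutVoxels, dropoutFactor = dropoutFactor,
      rngSeed = as.integer(rngSeed))
}

#' Generate a single synthetic run
#'
#' Draws the condition's latent region signals as correlated Gaussian series
#' (Cholesky factor of the effective coupling matrix), sets each voxel time
#' course to snr x its region's latent signal plus AR(1) Gaussian noise with
#' unit innovation variance (stationary start), adds the baseline intensity,
#' and attenuates the dropout block.  Deterministic given the config seed
#' and the (subject, condition) pair: each run has its own hashed RNG
#' stream, so adding subjects never perturbs existing runs.
#'
#' @param config a [SyntheticConfig-class].
#' @param subject subject index (1-based).
#' @param condition condition label or index.
#' @return a [BOLDRun-class].
#' @export
generateRun <- function(config, subject, condition) {
  if (is.character(condition))
    condition <- match(condition, config@conditions)
  if (is.na(condition) || condition < 1L ||
      condition > length(config@conditions))
    stop("unknown condition")
  condLabel <- config@conditions[condition]
  C <- effectiveCoupling(config, condLabel)
  R <- tryCatch(chol(C), error = function(e)
    stop(sprintf("effective coupling matrix for condition '%s' is not positive definite",
                 condLabel)))
  dm <- config@gridShape
  Vall <- prod(dm)
  T <- config@nTimepoints
  K <- length(config@regionBlocks)
  phi <- config@ar1Phi
  seed <- deriveStreamSeed(config@rngSeed, subject, condition)
  dat <- localSeed(seed, {
    latent <- matrix(stats::rnorm(T * K), T, K) %*% R   # T x K, cov = C
    eps <- matrix(stats::rnorm(Vall * T), Vall, T)
    noise <- eps
    noise[, 1] <- eps[, 1] / sqrt(1 - phi^2)            # stationary start
    for (t in 2:T) noise[, t] <- phi * noise[, t - 1] + eps[, t]
    sig <- matrix(0, Vall, T)
    for (k in seq_len(K)) {
      lin <- linearIndex(config@regionBlocks[[k]], dm)
      sig[lin, ] <- matrix(latent[, k], length(lin), T, byrow = TRUE)
    }
    out <- config@baseline + config@snr * sig + noise
    if (nrow(config@dropoutVoxels) > 0) {
      lin <- linearIndex(config@dropoutVoxels, dm)
      out[lin, ] <- out[lin, ] * config@dropoutFactor
    }
    out
  })
  BOLDRun(array(dat, dim = c(dm, T)),
          affine = diag(c(rep(config@voxelSizeMm, 3), 1)),
          trSeconds = config@trSeconds)
}

#' Generate a complete synthetic study
#'
#' One run per subject x condition plus ground truth (realized per-condition
#' coupling matrices, region voxel sets, hub label, dropout and modulated
#' voxel sets), a synthetic clinical score table and per-run motion traces
#' with rare spikes.  Fully deterministic given the config's seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param clinicalCellMeans cell means (PRE_OFF, PRE_ON, POST_OFF, POST_ON)
#'   for the synthetic clinical table.
#' @param clinicalSubjectSd,clinicalNoiseSd between-subject and residual SD
#'   of the clinical scores.
#' @param motionSpikeProb probability that a run contains one motion spike.
#' @param motionSpikeMm spike amplitude in mm.
#' @return a [SyntheticStudy-class].
#' @export
generateStudy <- function(config,
                          clinicalCellMeans = c(36, 11, 25, 10),
                          clinicalSubjectSd = 8, clinicalNoiseSd = 4,
                          motionSpikeProb = 0.15, motionSpikeMm = 3) {
  validObject(config)
  S <- config@nSubjects
  conds <- config@conditions
  runs <- list()
  motion <- list()
  for (s in seq_len(S)) for (k in seq_along(conds)) {
    nm <- paste(sprintf("sub%02d", s), conds[k], sep = ".")
    runs[[nm]] <- generateRun(config, s, k)
    mseed <- deriveStreamSeed(config@rngSeed, s, k + 1000L)
    spikes <- localSeed(mseed + 1L, {
      if (stats::runif(1) < motionSpikeProb)
        sample(2:(config@nTimepoints - 1L), 1L) else integer(0)
    })
    motion[[nm]] <- generateMotionTrace(config@nTimepoints,
                                        spikeTimes = spikes,
                                        spikeMm = motionSpikeMm,
                                        rngSeed = mseed)
  }
  clinical <- generateClinicalTable(S, clinicalCellMeans,
                                    clinicalSubjectSd, clinicalNoiseSd,
                                    deriveStreamSeed(config@rngSeed, 999983L, 1L))
  modulatedRegions <- unique(unlist(lapply(config@couplingDeltas, function(d) {
    nz <- which(d != 0, arr.ind = TRUE)
    rownames(d)[unique(as.vector(nz))]
  })))
  modulatedVoxels <- if (length(modulatedRegions))
    do.call(rbind, config@regionBlocks[modulatedRegions])
  else matrix(integer(0), 0, 3)
  truth <- list(
    coupling = stats::setNames(
      lapply(conds, function(cn) effectiveCoupling(config, cn)), conds),
    hubLabel = config@hubLabel,
    regionVoxels = config@regionBlocks,
    dropoutVoxels = config@dropoutVoxels,
    modulatedRegions = modulatedRegions,
    modulatedVoxels = modulatedVoxels)
  new("SyntheticStudy", runs = runs, truth = truth, clinical = clinical,
      motion = motion, config = config)
}

#' Generate a synthetic clinical score table
#'
#' score(subject, cell) = cell mean + subject random intercept + Gaussian
#' noise, rounded to integers and floored at 0 (integer UPDRS scoring).
#'
#' @param nSubjects number of subjects (>= 2).
#' @param cellMeans length-4 means for PRE_OFF, PRE_ON, POST_OFF, POST_ON.
#' @param subjectSd SD of the per-subject random intercept.
#' @param noiseSd residual SD.
#' @param rngSeed integer seed.
#' @return data.frame with columns subject, PRE_OFF, PRE_ON, POST_OFF,
#'   POST_ON.
#' @export
generateClinicalTable <- function(nSubjects, cellMeans, subjectSd = 8,
                                  noiseSd = 4, rngSeed = 1L) {
  stopifnot(nSubjects >= 2L, length(cellMeans) == 4L,
            subjectSd >= 0, noiseSd >= 0)
  localSeed(rngSeed, {
    b <- stats::rnorm(nSubjects, sd = subjectSd)
    scores <- outer(b, cellMeans, "+") +
      matrix(stats::rnorm(nSubjects * 4L, sd = noiseSd), nSubjects, 4L)
    scores <- round(scores)
    scores[scores < 0] <- 0
    data.frame(subject = sprintf("sub%02d", seq_len(nSubjects)),
               PRE_OFF = scores[, 1], PRE_ON = scores[, 2],
               POST_OFF = scores[, 3], POST_ON = scores[, 4])
  })
}

#' Generate a synthetic motion trace
#'
#' A smooth 6-parameter random walk (independent Gaussian increments per
#' parameter) with persistent translation jumps of `spikeMm` injected at
#' `spikeTimes` (a step change of the x translation from that frame on, so
#' each spike produces exactly one large framewise displacement).
#'
#' @param nTimepoints number of volumes.
#' @param spikeTimes integer frame indices (2..T) receiving a jump.
#' @param spikeMm jump amplitude in mm.
#' @param walkSdTransMm per-frame SD of translation increments (mm).
#' @param walkSdRotRad per-frame SD of rotation increments (radians).
#' @param rngSeed integer seed.
#' @return T x 6 matrix (translations mm, rotations rad).
#' @export
generateMotionTrace <- function(nTimepoints, spikeTimes = integer(0),
                                spikeMm = 3, walkSdTransMm = 0.02,
                                walkSdRotRad = 5e-4, rngSeed = 1L) {
  stopifnot(nTimepoints >= 2L,
            all(spikeTimes >= 2L & spikeTimes <= nTimepoints))
  localSeed(rngSeed, {
    inc <- cbind(matrix(stats::rnorm(nTimepoints * 3L, sd = walkSdTransMm),
                        nTimepoints, 3L),
                 matrix(stats::rnorm(nTimepoints * 3L, sd = walkSdRotRad),
                        nTimepoints, 3L))
    inc[1, ] <- 0
    trace <- apply(inc, 2, cumsum)
    for (st in spikeTimes)
      trace[st:nTimepoints, 1] <- trace[st:nTimepoints, 1] + spikeMm
    trace
  })
}
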