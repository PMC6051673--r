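#' @import methods
NULL

#' BOLDRun: a single 4D resting-state acquisition
#'
#' Container for one functional run: a 4D array (x, y, z, t) of BOLD
#' intensities together with the voxel-to-mm affine and the repetition time.
#' Runs are assumed co-registered; no realignment or normalisation is
#' performed by this package.
#'
#' @slot data 4D numeric array, dimensions (x, y, z, t).
#' @slot affine 4x4 voxel-to-mm transform (applied to 0-based voxel indices,
#'   NIfTI convention).
#' @slot trSeconds repetition time in seconds.
#' @export
setClass("BOLDRun",
  representation(data = "array", affine = "matrix", trSeconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array (x, y, z, t)")
    else if (dim(object@data)[4] < 2L)
      msg <- c(msg, "a run needs at least 2 timepoints")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    else if (abs(det(object@affine)) < .Machine$double.eps)
      msg <- c(msg, "affine must be invertible")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' VoxelMask: a binary analysis mask on the acquisition grid
#'
#' @slot data 3D logical array.
#' @slot affine 4x4 voxel-to-mm transform.
#' @export
setClass("VoxelMask",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "mask data must be a 3D array")
    if (!is.logical(object@data))
      msg <- c(msg, "mask data must be logical")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    if (length(msg)) msg else TRUE
  })

#' TimeSeriesMatrix: masked, standardized voxel time courses
#'
#' The substrate of all connectivity computations: a V x T matrix whose rows
#' are in-mask voxel time courses in a fixed linear order (column-major order
#' of the mask grid, identical for every run so maps are comparable).  When
#' standardized, every row has zero mean and unit L2 norm, so the inner
#' product of two rows is the Pearson correlation of the raw courses.
#'
#' @slot values V x T numeric matrix.
#' @slot voxelIndex V x 3 integer matrix of 1-based (x, y, z) grid indices,
#'   one row per matrix row.
#' @slot gridDim length-3 integer grid dimensions.
#' @slot affine 4x4 voxel-to-mm transform.
#' @slot standardized logical flag.
#' @slot dropped integer matrix (may have 0 rows) of voxel indices excluded
#'   for zero temporal variance.
#' @export
setClass("TimeSeriesMatrix",
  representation(values = "matrix", voxelIndex = "matrix",
                 gridDim = "integer", affine = "matrix",
                 standardized = "logical", dropped = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@voxelIndex) != nrow(object@values))
      msg <- c(msg, "voxelIndex must have one row per matrix row")
    if (ncol(object@voxelIndex) != 3L)
      msg <- c(msg, "voxelIndex must have 3 columns")
    if (length(object@gridDim) != 3L)
      msg <- c(msg, "gridDim must have length 3")
    if (isTRUE(object@standardized) && nrow(object@values) > 0) {
      rm <- rowMeans(object@values)
      nrm <- sqrt(rowSums(object@values^2))
      if (max(abs(rm)) > 1e-8 || max(abs(nrm - 1)) > 1e-8)
        msg <- c(msg, "standardized rows must have zero mean and unit L2 norm")
    }
    if (length(msg)) msg else TRUE
  })

#' ECMap: voxelwise eigenvector centrality for one run
#'
#' Components of the Perron eigenvector of the (non-negative) similarity
#' matrix, one value per in-mask voxel, scaled to unit L2 norm.
#'
#' @slot values length-V numeric vector, unit L2 norm.
#' @slot voxelIndex V x 3 integer matrix (as in [TimeSeriesMatrix-class]).
#' @slot gridDim,affine grid geometry for writing back to volume space.
#' @slot variant one of "add", "abs", "pos".
#' @slot iterations number of power iterations performed.
#' @slot converged logical convergence flag.
#' @slot uniquePerron FALSE when the dominant eigenspace was detected as
#'   (near-)degenerate, e.g. a reducible 'pos' similarity matrix.
#' @export
setClass("ECMap",
  representation(values = "numeric", voxelIndex = "matrix",
                 gridDim = "integer", affine = "matrix",
                 variant = "character", iterations = "integer",
                 converged = "logical", uniquePerron = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@variant %in% c("add", "abs", "pos"))
      msg <- c(msg, "variant must be one of 'add', 'abs', 'pos'")
    if (length(object@values) != nrow(object@voxelIndex))
      msg <- c(msg, "one value per voxel required")
    if (length(object@values) > 0 &&
        abs(sqrt(sum(object@values^2)) - 1) > 1e-8)
      msg <- c(msg, "EC values must have unit L2 norm")
    if (length(msg)) msg else TRUE
  })

#' StudyDesign: subjects x conditions flexible-factorial layout
#'
#' Over-parameterized indicator design with one column per condition followed
#' by one column per subject; one row per (subject, condition) map.  Rank is
#' S + K - 1; inference uses sum-to-zero contrasts over the condition columns.
#'
#' @slot subjects ordered subject labels.
#' @slot conditions ordered condition labels.
#' @slot design N x (K + S) 0/1 matrix, N = S * K, rows named
#'   "subject.condition".
#' @export
setClass("StudyDesign",
  representation(subjects = "character", conditions = "character",
                 design = "matrix"),
  validity = function(object) {
    S <- length(object@subjects); K <- length(object@conditions)
    msg <- character()
    if (anyDuplicated(object@subjects)) msg <- c(msg, "duplicate subject labels")
    if (anyDuplicated(object@conditions)) msg <- c(msg, "duplicate condition labels")
    if (!all(dim(object@design) == c(S * K, K + S)))
      msg <- c(msg, "design must be (S*K) x (K+S)")
    else {
      rs <- rowSums(object@design)
      if (!all(object@design %in% c(0, 1)) || !all(rs == 2))
        msg <- c(msg, "each row must set exactly one condition and one subject indicator")
    }
    if (length(msg)) msg else TRUE
  })

#' ContrastSpec: a sum-to-zero contrast over condition columns
#'
#' @slot weights named numeric vector over the design's condition labels
#'   (subject columns are implicitly weighted 0).
#' @slot label human-readable contrast name.
#' @export
setClass("ContrastSpec",
  representation(weights = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@weights)))
      msg <- c(msg, "weights must be named by condition")
    if (abs(sum(object@weights)) > 1e-10)
      msg <- c(msg, "contrast weights must sum to zero (estimability)")
    if (length(msg)) msg else TRUE
  })

#' StatMap: voxelwise statistics for one contrast
#'
#' @slot t,z,p,q length-V vectors: t statistic, probit z equivalent,
#'   one-sided p, Benjamini-Hochberg q within the analysis mask.
#' @slot dfError residual degrees of freedom (N - rank of design).
#' @slot contrast contrast label.
#' @slot voxelIndex,gridDim,affine grid geometry.
#' @export
setClass("StatMap",
  representation(t = "numeric", z = "numeric", p = "numeric", q = "numeric",
                 dfError = "integer", contrast = "character",
                 voxelIndex = "matrix", gridDim = "integer",
                 affine = "matrix"),
  validity = function(object) {
    V <- length(object@t)
    msg <- character()
    if (length(object@z) != V || length(object@p) != V || length(object@q) != V)
      msg <- c(msg, "t, z, p, q must have equal length")
    if (nrow(object@voxelIndex) != V)
      msg <- c(msg, "voxelIndex must have one row per voxel")
    if (V > 0 && any(object@q < object@p - 1e-12))
      msg <- c(msg, "q-values cannot be smaller than p-values")
    if (length(msg)) msg else TRUE
  })

#' SeedRegion: a seed mask derived from a significant cluster
#'
#' @slot mask [VoxelMask-class] of the seed voxels.
#' @slot sourceContrast label of the contrast that produced the cluster.
#' @slot peakMM mm coordinates of the cluster peak.
#' @export
setClass("SeedRegion",
  representation(mask = "VoxelMask", sourceContrast = "character",
                 peakMM = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!any(object@mask@data)) msg <- c(msg, "seed mask must be nonempty")
    if (length(object@peakMM) != 3L) msg <- c(msg, "peakMM must have length 3")
    if (length(msg)) msg else TRUE
  })

#' CorrelationMap: seed-to-voxel correlations for one run
#'
#' @slot values length-V vector of Pearson r (or Fisher z when transformed).
#' @slot voxelIndex,gridDim,affine grid geometry.
#' @slot subject,condition run labels.
#' @slot fisherZ TRUE when values are atanh-transformed.
#' @export
setClass("CorrelationMap",
  representation(values = "numeric", voxelIndex = "matrix",
                 gridDim = "integer", affine = "matrix",
                 subject = "character", condition = "character",
                 fisherZ = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != nrow(object@voxelIndex))
      msg <- c(msg, "one value per voxel required")
    if (!object@fisherZ && length(object@values) &&
        any(abs(object@values) > 1 + 1e-10))
      msg <- c(msg, "untransformed correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' SyntheticConfig: ground-truth specification of a synthetic BOLD study
#'
#' Describes a block-structured voxel network: disjoint region blocks driven
#' by correlated latent Gaussian signals (per-condition coupling matrices),
#' AR(1) voxel noise, an optional electrode-like signal-dropout region, plus
#' the acquisition geometry.  The configuration is the single source of
#' ground truth for downstream recovery tests.
#'
#' @slot gridShape length-3 integer voxel grid.
#' @slot voxelSizeMm isotropic voxel size (mm).
#' @slot nTimepoints number of volumes per run (>= 20).
#' @slot trSeconds repetition time.
#' @slot nSubjects number of subjects (>= 2).
#' @slot conditions ordered condition labels.
#' @slot regionBlocks named list of V x 3 integer matrices of voxel indices.
#' @slot baseCoupling symmetric unit-diagonal region coupling matrix.
#' @slot couplingDeltas named list (by condition) of additive symmetric
#'   changes to the coupling matrix (zero matrix if absent).
#' @slot hubLabel the region planted as network hub.
#' @slot ar1Phi AR(1) noise coefficient in [0, 1).
#' @slot snr latent-signal-to-noise amplitude ratio.
#' @slot baseline mean intensity added to every voxel (scanner units).
#' @slot dropoutVoxels integer matrix (possibly 0 rows) of attenuated voxels.
#' @slot dropoutFactor attenuation factor in [0, 1).
#' @slot rngSeed integer master seed; per-run streams are derived by stable
#'   hashing so adding subjects does not perturb existing runs.
#' @export
setClass("SyntheticConfig",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 nTimepoints = "integer", trSeconds = "numeric",
                 nSubjects = "integer", conditions = "character",
                 regionBlocks = "list", baseCoupling = "matrix",
                 couplingDeltas = "list", hubLabel = "character",
                 ar1Phi = "numeric", snr = "numeric", baseline = "numeric",
                 dropoutVoxels = "matrix", dropoutFactor = "numeric",
                 rngSeed = "integer"),
  validity = function(object) validateSyntheticConfig(object))

#' SyntheticStudy: a realized synthetic study with ground truth
#'
#' @slot runs named list ("subject.condition") of [BOLDRun-class] objects.
#' @slot truth list: per-condition realized coupling matrices, hub label,
#'   region voxel sets, dropout voxels, modulated voxel set.
#' @slot clinical data.frame of synthetic clinical scores.
#' @slot motion named list of T x 6 motion-parameter matrices.
#' @slot config the generating [SyntheticConfig-class].
#' @export
setClass("SyntheticStudy",
  representation(runs = "list", truth = "list", clinical = "data.frame",
                 motion = "list", config = "SyntheticConfig"))

setMethod("show", "BOLDRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BOLDRun: %d x %d x %d grid, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], object@trSeconds))
})

setMethod("show", "VoxelMask", function(object) {
  cat(sprintf("VoxelMask: %s grid, %d voxels in mask\n",
              paste(dim(object@data), collapse = " x "),
              sum(object@data)))
})

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf("TimeSeriesMatrix: %d voxels x %d timepoints (%s; %d dropped)\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) "standardized" else "raw",
              nrow(object@dropped)))
})

setMethod("show", "ECMap", function(object) {
  cat(sprintf("ECMap ('%s'): %d voxels, %d iterations, %s%s\n",
              object@variant, length(object@values), object@iterations,
              if (object@converged) "converged" else "NOT converged",
              if (object@uniquePerron) "" else " [degenerate Perron eigenspace]"))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d subjects x %d conditions (%d maps, rank %d)\n",
              length(object@subjects), length(object@conditions),
              nrow(object@design), qr(object@design)$rank))
})

setMethod("show", "ContrastSpec", function(object) {
  w <- object@weights[object@weights != 0]
  cat(sprintf("ContrastSpec '%s': %s\n", object@label,
              paste(sprintf("%+g*%s", w, names(w)), collapse = " ")))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap '%s': %d voxels, df = %d, %d voxels with q < 0.05\n",
              object@contrast, length(object@t), object@dfError,
              sum(object@q < 0.05)))
})

setMethod("show", "SeedRegion", function(object) {
  cat(sprintf("SeedRegion from '%s': %d voxels, peak at (%.1f, %.1f, %.1f) mm\n",
              object@sourceContrast, sum(object@mask@data),
              object@peakMM[1], object@peakMM[2], object@peakMM[3]))
})

setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf("CorrelationMap [%s, %s]: %d voxels (%s)\n",
              object@subject, object@condition, length(object@values),
              if (object@fisherZ) "Fisher z" else "Pearson r"))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d runs (%d subjects x %d conditions), hub = '%s'\n",
              length(object@runs), object@config@nSubjects,
              length(object@config@conditions), object@config@hubLabel))
})
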