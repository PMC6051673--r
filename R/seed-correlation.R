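#' Derive seed regions from a significant stat map
#'
#' Connected components of the strictly sub-threshold q-values
#' (q < `qThreshold`) become seed regions, each carrying its source contrast
#' and the mm coordinate of its peak (highest t).  An empty list (no
#' significant voxels) is a valid result, not an error.
#'
#' @param stat a [StatMap-class] carrying FDR-adjusted q-values.
#' @param qThreshold strict significance threshold (default 0.05).
#' @param connectivity component connectivity (default 18).
#' @return list of [SeedRegion-class] objects.
#' @export
seedsFromStatMap <- function(stat, qThreshold = 0.05, connectivity = 18L) {
  sig <- which(stat@q < qThreshold)
  if (!length(sig)) return(list())
  vox <- stat@voxelIndex[sig, , drop = FALSE]
  comp <- connectedComponents(vox, stat@gridDim, connectivity)
  lapply(sort(unique(comp)), function(cl) {
    sel <- comp == cl
    m <- array(FALSE, dim = stat@gridDim)
    m[vox[sel, , drop = FALSE]] <- TRUE
    peak <- vox[sel, , drop = FALSE][which.max(stat@t[sig[sel]]), ]
    new("SeedRegion",
        mask = VoxelMask(m, affine = stat@affine),
        sourceContrast = stat@contrast,
        peakMM = as.numeric(voxelToMM(peak, stat@affine)))
  })
}

#' Average BOLD time course of a seed region
#'
#' @param run a [BOLDRun-class].
#' @param seed a [SeedRegion-class] (or [VoxelMask-class]) on the same grid.
#' @return numeric vector of length T (unweighted voxel mean per timepoint).
#' @export
seedTimecourse <- function(run, seed) {
  mask <- if (is(seed, "SeedRegion")) seed@mask else seed
  d <- dim(run@data)
  stopIfGridMismatch(array(0, d[1:3]), mask@data, "run and seed")
  keep <- which(mask@data)
  if (!length(keep)) stop("empty seed region")
  colMeans(matrix(run@data, prod(d[1:3]), d[4])[keep, , drop = FALSE])
}

#' Seed-to-voxel correlation map
#'
#' Pearson correlation of every in-mask voxel time course with the seed
#' course; optionally Fisher z-transformed (atanh with r clipped to
#' +/-(1 - 1e-7)) for variance stabilization before group modelling.
#'
#' @param ts a standardized [TimeSeriesMatrix-class].
#' @param seedTc seed time course (length T).
#' @param fisher apply the Fisher transform (default TRUE).
#' @param subject,condition labels attached to the map.
#' @return a [CorrelationMap-class].
#' @export
correlationMap <- function(ts, seedTc, fisher = TRUE,
                           subject = "", condition = "") {
  if (!isTRUE(ts@standardized))
    stop("correlationMap requires a standardized TimeSeriesMatrix")
  if (length(seedTc) != ncol(ts@values))
    stop("seed time course length does not match the time-series matrix")
  s <- seedTc - mean(seedTc)
  nrm <- sqrt(sum(s^2))
  if (nrm == 0) stop("seed time course has zero variance")
  r <- as.numeric(ts@values %*% (s / nrm))
  vals <- if (fisher) atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)) else r
  new("CorrelationMap", values = vals, voxelIndex = ts@voxelIndex,
      gridDim = ts@gridDim, affine = ts@affine,
      subject = subject, condition = condition, fisherZ = fisher)
}
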