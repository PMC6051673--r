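#' Construct a BOLDRun
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm transform; default is a diagonal map with
#'   the given isotropic voxel size.
#' @param trSeconds repetition time in seconds.
#' @param voxelSizeMm isotropic voxel size used when `affine` is missing.
#' @return a [BOLDRun-class].
#' @export
BOLDRun <- function(data, affine = NULL, trSeconds = 3,
                    voxelSizeMm = 3) {
  if (is.null(affine)) affine <- diag(c(rep(voxelSizeMm, 3), 1))
  new("BOLDRun", data = data, affine = affine, trSeconds = trSeconds)
}

#' Construct a VoxelMask
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param affine 4x4 voxel-to-mm transform.
#' @return a [VoxelMask-class].
#' @export
VoxelMask <- function(data, affine = diag(4)) {
  storage.mode(data) <- "logical"
  new("VoxelMask", data = data, affine = affine)
}

#' Read / write 4D runs and 3D masks as NIfTI-1
#'
#' Thin wrappers around RNifti preserving the affine (sform) exactly and the
#' data to float precision.
#'
#' @param path file path (.nii or .nii.gz).
#' @param trSeconds repetition time to attach to the run.
#' @return `readBOLDRun` a [BOLDRun-class]; `readVoxelMask` a
#'   [VoxelMask-class]; the writers return `path` invisibly.
#' @name niftiIO
#' @export
readBOLDRun <- function(path, trSeconds = 3) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  BOLDRun(array(as.numeric(img), dim = dim(img)), affine = aff,
          trSeconds = trSeconds)
}

#' @rdname niftiIO
#' @param run a [BOLDRun-class].
#' @export
writeBOLDRun <- function(run, path) {
  img <- RNifti::asNifti(run@data)
  img <- RNifti::`sform<-`(img, structure(run@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname niftiIO
#' @export
readVoxelMask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  VoxelMask(array(as.numeric(img) != 0, dim = dim(img)), affine = aff)
}

#' @rdname niftiIO
#' @param mask a [VoxelMask-class].
#' @export
writeVoxelMask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask@data), dim = dim(mask@data)))
  img <- RNifti::`sform<-`(img, structure(mask@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Susceptibility-artifact intensity mask
#'
#' Builds a per-run mask that excludes voxels with severe signal dropout
#' (e.g. near DBS electrodes): a voxel is kept iff its temporal-mean
#' intensity reaches `fraction` of the robust maximum of the temporal-mean
#' image, defined as its 99th percentile so single hot voxels cannot inflate
#' the reference.
#'
#' @param run a [BOLDRun-class].
#' @param fraction threshold fraction in (0, 1); default 0.4.
#' @param robustQuantile quantile defining the robust maximum.
#' @return a [VoxelMask-class].
#' @export
intensityMask <- function(run, fraction = 0.4, robustQuantile = 0.99) {
  stopifnot(fraction > 0, fraction < 1)
  d <- dim(run@data)
  tmean <- rowMeans(matrix(run@data, prod(d[1:3]), d[4]))
  ref <- stats::quantile(tmean, robustQuantile, names = FALSE)
  keep <- tmean >= fraction * ref
  if (sum(keep) < 2L)
    stop(sprintf("intensity mask at fraction %.3g leaves %d voxel(s); all or nearly all voxels excluded",
                 fraction, sum(keep)))
  VoxelMask(array(keep, dim = d[1:3]), affine = run@affine)
}

#' Combine masks with logical AND
#'
#' `combineMasksAll` intersects any number of individual masks (e.g. the
#' per-patient post-surgery masks); `maskConjunction` is the two-input
#' conjunction with an anatomical search-space mask.  Voxels survive only if
#' present in every input.
#'
#' @param masks list of [VoxelMask-class] objects on a common grid.
#' @return a [VoxelMask-class].
#' @export
combineMasksAll <- function(masks) {
  stopifnot(length(masks) >= 1L)
  out <- masks[[1]]@data
  for (m in masks[-1]) {
    stopIfGridMismatch(out, m@data, "masks")
    out <- out & m@data
  }
  VoxelMask(out, affine = masks[[1]]@affine)
}

#' @rdname combineMasksAll
#' @param mask,anatomical two [VoxelMask-class] objects on a common grid.
#' @export
maskConjunction <- function(mask, anatomical) {
  stopIfGridMismatch(mask@data, anatomical@data, "mask and anatomical mask")
  VoxelMask(mask@data & anatomical@data, affine = mask@affine)
}

# reflective-boundary 1D convolution along dimension `axis` of a 3D array
convolveAxis <- function(vol, kernel, axis) {
  n <- dim(vol)[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = dim(vol))
  for (o in -r:r) {
    j <- seq_len(n) + o
    # mirror boundary (dcba | abcd); repeat for kernels wider than the axis
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    idx <- switch(axis,
                  vol[j, , , drop = FALSE],
                  vol[, j, , drop = FALSE],
                  vol[, , j, drop = FALSE])
    out <- out + kernel[o + r + 1L] * idx
  }
  out
}

gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox < 1e-8) return(1)
  r <- max(1L, ceiling(5 * sigmaVox))   # 5 sigma: truncated tail < 3e-7
  k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

#' Spatial Gaussian smoothing
#'
#' Convolves every volume with a separable Gaussian kernel specified by its
#' full width at half maximum in mm (sigma = FWHM / (2 sqrt(2 ln 2))); the
#' kernel width per axis is derived from the affine's voxel sizes.
#' Reflective boundary handling preserves the spatial sum of each volume.
#'
#' @param run a [BOLDRun-class].
#' @param fwhmMm kernel full width at half maximum in mm (e.g. 8).
#' @return a smoothed [BOLDRun-class].
#' @export
gaussianSmooth <- function(run, fwhmMm) {
  stopifnot(fwhmMm > 0)
  sigmaMm <- fwhmToSigma(fwhmMm)
  voxSize <- sqrt(colSums(run@affine[1:3, 1:3]^2))
  kernels <- lapply(1:3, function(a) gaussKernel1d(sigmaMm / voxSize[a]))
  d <- dim(run@data)
  out <- run@data
  for (t in seq_len(d[4])) {
    vol <- out[, , , t]
    for (a in 1:3)
      if (length(kernels[[a]]) > 1L) vol <- convolveAxis(vol, kernels[[a]], a)
    out[, , , t] <- vol
  }
  BOLDRun(out, affine = run@affine, trSeconds = run@trSeconds)
}

#' Extract a standardized time-series matrix
#'
#' Pulls the in-mask voxel time courses into a V x T matrix (fixed
#' column-major voxel order), demeans each row and scales it to unit L2 norm
#' so that row inner products are Pearson correlations.  Voxels with zero
#' temporal variance are dropped and reported in the `dropped` slot.
#'
#' @param run a [BOLDRun-class].
#' @param mask a [VoxelMask-class] on the same grid.
#' @return a [TimeSeriesMatrix-class].
#' @export
extractTimeSeries <- function(run, mask) {
  d <- dim(run@data)
  stopIfGridMismatch(array(0, d[1:3]), mask@data, "run and mask")
  keep <- which(mask@data)
  vox <- indexToVoxel(keep, d[1:3])
  M <- matrix(run@data, prod(d[1:3]), d[4])[keep, , drop = FALSE]
  Mc <- M - rowMeans(M)
  nrm <- sqrt(rowSums(Mc^2))
  bad <- nrm == 0
  if (sum(!bad) < 2L)
    stop("fewer than 2 voxels with temporal variance survive the mask")
  vals <- Mc[!bad, , drop = FALSE] / nrm[!bad]
  new("TimeSeriesMatrix",
      values = vals,
      voxelIndex = vox[!bad, , drop = FALSE],
      gridDim = as.integer(d[1:3]),
      affine = run@affine,
      standardized = TRUE,
      dropped = vox[bad, , drop = FALSE])
}

#' Construct a TimeSeriesMatrix from a bare matrix
#'
#' Convenience constructor for matrix-level workflows (e.g. toy problems):
#' rows are voxel time courses on an implicit V x 1 x 1 grid unless explicit
#' voxel coordinates are given.  Standardization (demean + unit L2 norm per
#' row) is applied by default; rows with zero variance are an error here —
#' use [extractTimeSeries()] for the dropping behaviour.
#'
#' @param values V x T numeric matrix.
#' @param voxelIndex optional V x 3 integer coordinate matrix.
#' @param gridDim optional length-3 grid dimensions.
#' @param affine 4x4 transform (default identity).
#' @param standardize demean and rescale rows (default TRUE).
#' @return a [TimeSeriesMatrix-class].
#' @export
timeSeriesMatrix <- function(values, voxelIndex = NULL, gridDim = NULL,
                             affine = diag(4), standardize = TRUE) {
  values <- as.matrix(values)
  V <- nrow(values)
  if (is.null(voxelIndex))
    voxelIndex <- cbind(seq_len(V), 1L, 1L)
  if (is.null(gridDim))
    gridDim <- c(max(voxelIndex[, 1]), max(voxelIndex[, 2]),
                 max(voxelIndex[, 3]))
  if (standardize) {
    if (any(apply(values, 1, stats::sd) == 0))
      stop("zero-variance rows cannot be standardized")
    values <- standardizeRows(values)
  }
  new("TimeSeriesMatrix", values = values,
      voxelIndex = cbind(as.integer(voxelIndex[, 1]),
                         as.integer(voxelIndex[, 2]),
                         as.integer(voxelIndex[, 3])),
      gridDim = as.integer(gridDim), affine = affine,
      standardized = standardize,
      dropped = matrix(integer(0), 0, 3))
}

#' Put per-voxel values back into volume space
#'
#' @param values length-V numeric vector.
#' @param voxelIndex V x 3 integer matrix of grid coordinates.
#' @param dm length-3 grid dimensions.
#' @param fill value for out-of-mask voxels (default `NA`).
#' @return 3D array.
#' @export
mapToVolume <- function(values, voxelIndex, dm, fill = NA_real_) {
  out <- array(fill, dim = dm)
  out[cbind(voxelIndex)] <- values
  out
}

#' Write an EC, correlation or stat map as NIfTI-1
#'
#' Out-of-mask voxels are written as NaN.  For a [StatMap-class] one file per
#' statistic (t, z, q) is produced with suffixes before the extension.
#'
#' @param map an [ECMap-class], [CorrelationMap-class] or [StatMap-class].
#' @param path output path (.nii / .nii.gz).
#' @return the path(s) written, invisibly.
#' @export
writeMapNifti <- function(map, path) {
  writeOne <- function(values, p) {
    vol <- mapToVolume(values, map@voxelIndex, map@gridDim, fill = NaN)
    img <- RNifti::asNifti(vol)
    img <- RNifti::`sform<-`(img, structure(map@affine, code = 2L))
    RNifti::writeNifti(img, p, datatype = "float")
    p
  }
  if (is(map, "StatMap")) {
    stub <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- substr(path, nchar(stub) + 1L, nchar(path))
    if (ext == "") ext <- ".nii"
    ps <- c(writeOne(map@t, paste0(stub, "_t", ext)),
            writeOne(map@z, paste0(stub, "_z", ext)),
            writeOne(map@q, paste0(stub, "_q", ext)))
    return(invisible(ps))
  }
  invisible(writeOne(map@values, path))
}
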