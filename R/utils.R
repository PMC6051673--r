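# Internal helpers shared across modules.

# FWHM (mm) -> Gaussian sigma (mm)
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# mm coordinates of 1-based voxel indices under the NIfTI convention
# (affine applies to 0-based indices).  vox: n x 3 matrix or length-3 vector.
voxelToMM <- function(vox, affine) {
  if (is.null(dim(vox))) vox <- matrix(vox, nrow = 1L)
  hom <- cbind(vox - 1, 1)
  mm <- hom %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

# column-major linear index of n x 3 voxel coordinates on grid `dm`
linearIndex <- function(vox, dm) {
  if (is.null(dim(vox))) vox <- matrix(vox, nrow = 1L)
  (vox[, 1] - 1) + dm[1] * ((vox[, 2] - 1) + dm[2] * (vox[, 3] - 1)) + 1
}

# inverse of linearIndex
indexToVoxel <- function(idx, dm) {
  idx0 <- idx - 1
  x <- idx0 %% dm[1]
  y <- (idx0 %/% dm[1]) %% dm[2]
  z <- idx0 %/% (dm[1] * dm[2])
  cbind(x, y, z) + 1L
}

# Per-run RNG stream: a stable integer hash of (master seed, subject index,
# condition index) so that adding subjects or reordering the generation loop
# never perturbs existing runs.  Kept below 2^31 - 1.
deriveStreamSeed <- function(masterSeed, subjectIndex, conditionIndex) {
  m <- 2147483647
  h <- (as.numeric(masterSeed) %% m)
  h <- (h * 48271 + subjectIndex * 69621 + conditionIndex * 16807 + 12345) %% m
  as.integer(h)
}

# demean rows and scale to unit L2 norm; rows with zero variance -> NA rows
standardizeRows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  x / nrm
}

# evaluate an expression with a temporary RNG state, restoring the caller's
localSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
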