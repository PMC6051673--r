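#' Voxelwise eigenvector centrality by power iteration
#'
#' Computes the Perron eigenvector of the transformed similarity matrix
#' f(C), where C = X Xt is the full voxel-by-voxel Pearson correlation
#' matrix of the standardized time courses (unit diagonal included) and f is
#' one of the three non-negativity variants:
#' \describe{
#'   \item{add}{r -> r + 1 (strictly positive matrix, unique Perron vector)}
#'   \item{abs}{r -> |r|}
#'   \item{pos}{r -> max(r, 0)}
#' }
#' Power iteration starts from a uniform positive vector, normalizes every
#' iterate to unit L2 norm, and stops when successive iterates differ by
#' less than `tol` in the sup norm.  For 'add' the product f(C) v is
#' evaluated matrix-free as X (Xt v) + sum(v) * 1, costing O(VT) per
#' iteration without ever materializing C.  For 'abs'/'pos' rows of C are
#' formed in blocks of `chunkRows`, transformed, multiplied and discarded,
#' so peak memory never holds more than `chunkRows` full rows.
#'
#' A reducible 'pos' similarity matrix (some voxel non-positively correlated
#' with everything, or disconnected blocks) can have a degenerate dominant
#' eigenspace; the result then carries `uniquePerron = FALSE`, detected by
#' estimating the second eigenvalue on the deflated operator.
#'
#' @param ts a standardized [TimeSeriesMatrix-class].
#' @param variant "add" (default), "abs" or "pos".
#' @param tol sup-norm convergence tolerance (default 1e-9).
#' @param maxIter iteration cap (default 10000); non-convergence returns the
#'   last iterate with `converged = FALSE`.
#' @param chunkRows block size for the chunked 'abs'/'pos' path.
#' @return an [ECMap-class] with unit-L2-norm values.
#' @seealso [ecMapDense()] for the dense reference implementation.
#' @export
ecMap <- function(ts, variant = c("add", "abs", "pos"), tol = 1e-9,
                  maxIter = 10000L, chunkRows = 256L) {
  variant <- match.arg(variant)
  if (!isTRUE(ts@standardized))
    stop("ecMap requires a standardized TimeSeriesMatrix")
  stopifnot(tol > 0)
  X <- ts@values
  V <- nrow(X)
  if (V < 2L) stop("need at least 2 voxels")

  matvec <- if (variant == "add") {
    function(v) as.numeric(X %*% crossprod(X, v)) + sum(v)
  } else {
    f <- if (variant == "abs") abs else function(r) pmax(r, 0)
    starts <- seq(1L, V, by = chunkRows)
    function(v) {
      out <- numeric(V)
      for (s in starts) {
        i <- s:min(s + chunkRows - 1L, V)
        # block of similarity rows; unit diagonal is exact by construction
        Cblk <- tcrossprod(X[i, , drop = FALSE], X)
        out[i] <- f(Cblk) %*% v
      }
      out
    }
  }

  v <- rep(1 / sqrt(V), V)
  iterations <- 0L
  converged <- FALSE
  repeat {
    w <- matvec(v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("similarity operator annihilated the iterate; degenerate input")
    w <- w / nw
    iterations <- iterations + 1L
    if (max(abs(w - v)) < tol) { v <- w; converged <- TRUE; break }
    v <- w
    if (iterations >= maxIter) break
  }
  if (sum(v) < 0) v <- -v

  uniquePerron <- TRUE
  if (variant != "add") {
    lambda1 <- sum(v * matvec(v))
    lambda2 <- estimateSecondEigenvalue(matvec, v, lambda1, V)
    if (is.finite(lambda2) && lambda1 > 0 &&
        lambda2 / lambda1 > 1 - 1e-6) uniquePerron <- FALSE
    if (any(v < 1e-12) && variant == "pos") uniquePerron <- FALSE
  }
  if (!converged) uniquePerron <- FALSE
  if (!converged)
    warning(sprintf("power iteration did not converge in %d iterations", maxIter))
  if (!uniquePerron && converged)
    warning("dominant eigenspace appears degenerate; the Perron vector is not unique")

  new("ECMap", values = v, voxelIndex = ts@voxelIndex,
      gridDim = ts@gridDim, affine = ts@affine, variant = variant,
      iterations = iterations, converged = converged,
      uniquePerron = uniquePerron)
}

# power iteration on the deflated operator A - lambda1 v vT, started from a
# deterministic vector orthogonalized against v; returns |lambda2| estimate
estimateSecondEigenvalue <- function(matvec, v, lambda1, V, nIter = 30L) {
  u <- sin(seq_len(V))            # deterministic, generic start
  u <- u - sum(u * v) * v
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(NA_real_)
  u <- u / nu
  lam <- NA_real_
  for (i in seq_len(nIter)) {
    w <- matvec(u) - lambda1 * sum(v * u) * v
    w <- w - sum(w * v) * v       # re-orthogonalize against drift
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)
    lam <- nw
    u <- w / nw
  }
  abs(lam)
}

#' Dense reference implementation of eigenvector centrality
#'
#' Builds the full transformed similarity matrix f(C) and extracts the
#' eigenvector of the largest eigenvalue by dense symmetric
#' eigendecomposition, oriented positive.  Guarded to small problems; used
#' as the independent cross-check for [ecMap()].
#'
#' @inheritParams ecMap
#' @param maxVoxels guard on the number of voxels (default 2000).
#' @return an [ECMap-class].
#' @export
ecMapDense <- function(ts, variant = c("add", "abs", "pos"),
                       maxVoxels = 2000L) {
  variant <- match.arg(variant)
  if (!isTRUE(ts@standardized))
    stop("ecMapDense requires a standardized TimeSeriesMatrix")
  X <- ts@values
  V <- nrow(X)
  if (V > maxVoxels)
    stop(sprintf("dense path guarded to %d voxels (got %d)", maxVoxels, V))
  C <- tcrossprod(X)
  diag(C) <- 1
  A <- switch(variant,
              add = C + 1,
              abs = abs(C),
              pos = pmax(C, 0))
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  gap <- if (V >= 2) e$values[2] / e$values[1] else 0
  new("ECMap", values = v, voxelIndex = ts@voxelIndex,
      gridDim = ts@gridDim, affine = ts@affine, variant = variant,
      iterations = 0L, converged = TRUE,
      uniquePerron = !(is.finite(gap) && gap > 1 - 1e-6))
}
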