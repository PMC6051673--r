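#' Build a flexible-factorial study design
#'
#' One row per (subject, condition) map, ordered subject-major; columns are
#' the K condition indicators followed by the S subject indicators.  The
#' design is deliberately over-parameterized (rank S + K - 1); estimable
#' contrasts are sum-to-zero weightings of the condition columns.
#'
#' @param subjects character vector of subject labels.
#' @param conditions character vector of condition labels.
#' @return a [StudyDesign-class].
#' @export
buildDesign <- function(subjects, conditions) {
  subjects <- as.character(subjects); conditions <- as.character(conditions)
  if (anyDuplicated(subjects)) stop("duplicate subject labels")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  stopifnot(length(subjects) >= 2L, length(conditions) >= 2L)
  S <- length(subjects); K <- length(conditions)
  X <- matrix(0, S * K, K + S,
              dimnames = list(NULL, c(conditions, subjects)))
  rn <- character(S * K)
  r <- 0L
  for (s in seq_len(S)) for (k in seq_len(K)) {
    r <- r + 1L
    X[r, k] <- 1
    X[r, K + s] <- 1
    rn[r] <- paste(subjects[s], conditions[k], sep = ".")
  }
  rownames(X) <- rn
  new("StudyDesign", subjects = subjects, conditions = conditions, design = X)
}

#' Define a condition contrast
#'
#' @param weights named numeric vector of weights over condition labels;
#'   omitted conditions get weight 0.  Must sum to zero.
#' @param label contrast name.
#' @return a [ContrastSpec-class].
#' @export
contrastSpec <- function(weights, label = NULL) {
  if (is.null(label))
    label <- paste(sprintf("%+g*%s", weights[weights != 0],
                           names(weights)[weights != 0]), collapse = " ")
  new("ContrastSpec", weights = weights, label = label)
}

# full-length contrast vector (condition weights then zero subject weights)
expandContrast <- function(contrast, design) {
  K <- length(design@conditions); S <- length(design@subjects)
  cvec <- numeric(K + S)
  names(cvec) <- colnames(design@design)
  unknown <- setdiff(names(contrast@weights), design@conditions)
  if (length(unknown))
    stop("contrast names not in design conditions: ",
         paste(unknown, collapse = ", "))
  cvec[names(contrast@weights)] <- contrast@weights
  cvec
}

#' Check contrast estimability
#'
#' A contrast is estimable under the over-parameterized design iff its
#' full-length vector lies in the row space of the design matrix, which for
#' this layout reduces to: zero weights on subject columns and condition
#' weights summing to zero.
#'
#' @param design a [StudyDesign-class].
#' @param contrast a [ContrastSpec-class].
#' @return logical.
#' @export
isEstimable <- function(design, contrast) {
  cvec <- expandContrast(contrast, design)
  X <- design@design
  Xp <- pseudoInverse(X)
  proj <- crossprod(X, t(Xp)) %*% cvec   # row-space projector X' X+' applied
  max(abs(proj - cvec)) < 1e-8
}

# Moore-Penrose pseudoinverse via SVD
pseudoInverse <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit the voxelwise flexible-factorial GLM
#'
#' Ordinary least squares per voxel with coefficients obtained through the
#' Moore-Penrose pseudoinverse (the design is rank-deficient by
#' construction).  Residual variance is RSS / dfError with
#' dfError = N - rank(X); no variance pooling or nonsphericity correction is
#' applied.
#'
#' @param maps V x N numeric matrix of per-run maps (columns ordered as the
#'   design rows).
#' @param design a [StudyDesign-class].
#' @return a list of class "ecmapGLMFit": `coef` (P x V), `residVar` (V),
#'   `dfError`, `rank`, `xtxPinv`, `design`.
#' @export
fitGLM <- function(maps, design) {
  X <- design@design
  N <- nrow(X)
  if (ncol(maps) != N)
    stop(sprintf("maps has %d columns but design has %d rows", ncol(maps), N))
  Xp <- pseudoInverse(X)
  rankX <- qr(X)$rank
  dfError <- N - rankX
  if (dfError < 1L) stop("no residual degrees of freedom (N <= rank)")
  Y <- t(maps)                      # N x V
  B <- Xp %*% Y                     # P x V
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  # exact fits leave numerically-zero residuals; flush them so downstream
  # t statistics become 0/0-free (t := 0 where the data are fit exactly)
  scale <- mean(Y^2)
  if (scale > 0) rss[rss < 1e-20 * scale] <- 0
  structure(list(coef = B, residVar = rss / dfError,
                 dfError = as.integer(dfError), rank = rankX,
                 xtxPinv = Xp %*% t(Xp), design = design),
            class = "ecmapGLMFit")
}

#' One-sided t/z/FDR statistics for a contrast
#'
#' t = c'B / sqrt(sigma2 * c'(X'X)+ c) per voxel; one-sided p from the t
#' distribution with dfError degrees of freedom; z is the standard-normal
#' deviate with the same upper-tail probability, computed in log space so
#' large t do not saturate; q is the Benjamini-Hochberg adjustment across
#' the in-mask voxels.
#'
#' @param fit result of [fitGLM()].
#' @param contrast a [ContrastSpec-class].
#' @param voxelIndex,dm,affine grid geometry to attach (optional; defaults
#'   to a bare 1D layout).
#' @return a [StatMap-class].
#' @export
contrastTMap <- function(fit, contrast, voxelIndex = NULL, dm = NULL,
                         affine = NULL) {
  design <- fit$design
  if (!isEstimable(design, contrast))
    stop(sprintf("contrast '%s' is not estimable under this design",
                 contrast@label))
  cvec <- expandContrast(contrast, design)
  est <- as.numeric(crossprod(cvec, fit$coef))
  cvc <- as.numeric(crossprod(cvec, fit$xtxPinv %*% cvec))
  se <- sqrt(fit$residVar * cvc)
  tstat <- ifelse(se > 0, est / se, 0)
  p <- stats::pt(tstat, df = fit$dfError, lower.tail = FALSE)
  z <- tToZ(tstat, fit$dfError)
  q <- stats::p.adjust(p, method = "BH")
  V <- length(tstat)
  if (is.null(voxelIndex)) voxelIndex <- cbind(seq_len(V), 1L, 1L)
  if (is.null(dm)) dm <- c(V, 1L, 1L)
  if (is.null(affine)) affine <- diag(4)
  new("StatMap", t = tstat, z = z, p = p, q = q,
      dfError = fit$dfError, contrast = contrast@label,
      voxelIndex = voxelIndex, gridDim = as.integer(dm), affine = affine)
}

#' Convert t statistics to z scores
#'
#' Probit transform of the upper-tail t probability, evaluated in log space
#' so that very large t values convert without saturating to Inf.
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom.
#' @return numeric vector of z scores.
#' @export
tToZ <- function(t, df) {
  lp <- stats::pt(t, df = df, lower.tail = FALSE, log.p = TRUE)
  stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' The standard contrast battery
#'
#' The eleven directed condition contrasts of the DBS-vs-levodopa analysis:
#' unilateral ON differences against the levodopa ON state, the OFF-OFF
#' (microlesion) difference, the two unilateral difference-of-difference
#' interactions, the weighted bilateral ON contrast
#' (POST_ON_left + POST_ON_right - 2 PRE_ON) and its interaction, and the
#' reverse-direction contrasts testing for decreases.
#'
#' @param conditions the five condition labels (defaults to the standard
#'   PRE/POST x OFF/ON(left/right) layout).
#' @return named list of [ContrastSpec-class] objects.
#' @export
contrastBattery <- function(conditions = c("PRE_OFF", "PRE_ON", "POST_OFF",
                                           "POST_ON_left", "POST_ON_right")) {
  stopifnot(length(conditions) == 5L)
  w <- function(...) {
    x <- c(...)
    structure(as.numeric(x), names = conditions[seq_along(x)])
  }
  cn <- conditions
  mk <- function(weights, label) contrastSpec(weights, label)
  list(
    POST_ON_left_minus_PRE_ON =
      mk(structure(c(-1, 1), names = cn[c(2, 4)]), "POST_ON_left - PRE_ON"),
    POST_ON_right_minus_PRE_ON =
      mk(structure(c(-1, 1), names = cn[c(2, 5)]), "POST_ON_right - PRE_ON"),
    POST_OFF_minus_PRE_OFF =
      mk(structure(c(-1, 1), names = cn[c(1, 3)]), "POST_OFF - PRE_OFF"),
    interaction_left =
      mk(structure(c(1, -1, -1, 1), names = cn[c(1, 2, 3, 4)]),
         "(POST_ON_left - PRE_ON) - (POST_OFF - PRE_OFF)"),
    interaction_right =
      mk(structure(c(1, -1, -1, 1), names = cn[c(1, 2, 3, 5)]),
         "(POST_ON_right - PRE_ON) - (POST_OFF - PRE_OFF)"),
    POST_ON_minus_PRE_ON =
      mk(structure(c(-2, 1, 1), names = cn[c(2, 4, 5)]),
         "POST_ON - PRE_ON (weighted)"),
    interaction_weighted =
      mk(structure(c(2, -2, -2, 1, 1), names = cn),
         "(POST_ON - PRE_ON) - 2*(POST_OFF - PRE_OFF) (weighted)"),
    PRE_ON_minus_POST_ON_left =
      mk(structure(c(1, -1), names = cn[c(2, 4)]), "PRE_ON - POST_ON_left"),
    PRE_ON_minus_POST_ON_right =
      mk(structure(c(1, -1), names = cn[c(2, 5)]), "PRE_ON - POST_ON_right"),
    PRE_ON_minus_POST_ON =
      mk(structure(c(2, -1, -1), names = cn[c(2, 4, 5)]),
         "PRE_ON - POST_ON (weighted)"),
    PRE_OFF_minus_POST_OFF =
      mk(structure(c(1, -1), names = cn[c(1, 3)]), "PRE_OFF - POST_OFF")
  )
}

#' Benjamini-Hochberg FDR
#'
#' Step-up q-values (min over j >= i of p(j) * m / j on the sorted p) and
#' the rejection set at level `qLevel`.
#'
#' @param p vector of p-values in [0, 1].
#' @param qLevel FDR level (default 0.05).
#' @return list with `q` (adjusted values, original order) and `reject`
#'   (logical mask, q <= qLevel).
#' @export
fdrBH <- function(p, qLevel = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= qLevel)
}

# 18-connected components (faces + edges, SPM convention) among a set of
# voxels; returns an integer component label per voxel row
connectedComponents <- function(vox, dm, connectivity = 18L) {
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d1 <- abs(offs[, 1]) + abs(offs[, 2]) + abs(offs[, 3])
  offs <- switch(as.character(connectivity),
                 "6"  = offs[d1 == 1, , drop = FALSE],
                 "18" = offs[d1 >= 1 & d1 <= 2, , drop = FALSE],
                 "26" = offs[d1 >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  lin <- linearIndex(vox, dm)
  lookup <- structure(seq_len(n), names = as.character(lin))
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
          nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    j <- lookup[as.character(linearIndex(nb[ok, , drop = FALSE], dm))]
    i <- seq_len(n)[ok]
    hit <- !is.na(j)
    if (any(hit)) edges <- c(edges, rbind(i[hit], j[hit]))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Extract significant clusters and local maxima
#'
#' Groups rejected voxels into 18-connected components and reports, per
#' cluster, the size k in voxels, the peak (highest t) in mm coordinates,
#' and up to `maxPeaks` local maxima greedily selected in descending t
#' subject to a pairwise distance greater than `minPeakDistMm`.
#'
#' @param stat a [StatMap-class].
#' @param reject logical rejection mask over the stat map's voxels (default:
#'   q <= qLevel).
#' @param qLevel used when `reject` is missing.
#' @param connectivity 6, 18 (default) or 26.
#' @param maxPeaks maxima reported per cluster (default 3).
#' @param minPeakDistMm minimum inter-maximum distance (default 8).
#' @param excludeVoxels optional integer matrix of voxel coordinates to
#'   exclude from peak reporting (e.g. seed voxels with trivial
#'   self-correlation).
#' @return data.frame with columns cluster, x, y, z (mm), T, Z, k, q and a
#'   logical `isPeak` marking each cluster's global maximum; zero rows when
#'   nothing is rejected.
#' @export
extractClusters <- function(stat, reject = NULL, qLevel = 0.05,
                            connectivity = 18L, maxPeaks = 3L,
                            minPeakDistMm = 8, excludeVoxels = NULL) {
  if (is.null(reject)) reject <- stat@q <= qLevel
  stopifnot(length(reject) == length(stat@t))
  if (!is.null(excludeVoxels) && nrow(excludeVoxels)) {
    ex <- linearIndex(excludeVoxels, stat@gridDim)
    reject <- reject & !(linearIndex(stat@voxelIndex, stat@gridDim) %in% ex)
  }
  idx <- which(reject)
  empty <- data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), T = numeric(0), Z = numeric(0),
                      k = integer(0), q = numeric(0), isPeak = logical(0))
  if (!length(idx)) return(empty)
  vox <- stat@voxelIndex[idx, , drop = FALSE]
  comp <- connectedComponents(vox, stat@gridDim, connectivity)
  rows <- list()
  for (cl in sort(unique(comp))) {
    sel <- comp == cl
    tvals <- stat@t[idx[sel]]
    mm <- voxelToMM(vox[sel, , drop = FALSE], stat@affine)
    ord <- order(tvals, decreasing = TRUE)
    chosen <- integer(0)
    for (cand in ord) {
      if (length(chosen) >= maxPeaks) break
      if (!length(chosen) ||
          all(sqrt(rowSums((mm[chosen, , drop = FALSE] -
                            matrix(mm[cand, ], length(chosen), 3,
                                   byrow = TRUE))^2)) > minPeakDistMm))
        chosen <- c(chosen, cand)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl,
      x = mm[chosen, 1], y = mm[chosen, 2], z = mm[chosen, 3],
      T = tvals[chosen], Z = stat@z[idx[sel]][chosen],
      k = sum(sel), q = stat@q[idx[sel]][chosen],
      isPeak = seq_along(chosen) == 1L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cluster table as TSV
#'
#' @param clusters data.frame from [extractClusters()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
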