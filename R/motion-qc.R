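#' Framewise displacement
#'
#' FD at frame t is the sum of absolute frame-to-frame changes of the three
#' translations (mm) plus the three rotations converted to arc length on a
#' sphere of radius `headRadiusMm` (default 50 mm).  A run of T volumes
#' yields T - 1 FD values.  Rotations are assumed in radians (the SPM
#' convention); set `degrees = TRUE` to convert first.
#'
#' @param trace T x 6 numeric matrix: translations x, y, z in mm, then
#'   rotations pitch, roll, yaw.
#' @param headRadiusMm rotation-to-arc-length radius.
#' @param degrees TRUE when rotation columns are in degrees.
#' @return numeric vector of length T - 1.
#' @export
framewiseDisplacement <- function(trace, headRadiusMm = 50,
                                  degrees = FALSE) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L || nrow(trace) < 2L)
    stop("motion trace must be a T x 6 matrix with T >= 2")
  rot <- trace[, 4:6, drop = FALSE]
  if (degrees) rot <- rot * pi / 180
  dTrans <- abs(diff(trace[, 1:3, drop = FALSE]))
  dRot <- abs(diff(rot))
  rowSums(dTrans) + headRadiusMm * rowSums(dRot)
}

#' Summarize a framewise-displacement series
#'
#' The four per-run summaries: mean FD, maximum FD, maximum FD after
#' discarding the largest `trimFraction` of values (ceil(trimFraction * n)
#' values removed; ties broken by keeping earlier frames), and the count of
#' FD values exceeding `spikeMm`.
#'
#' @param fd numeric FD series.
#' @param spikeMm spike threshold in mm (default 2).
#' @param trimFraction fraction of largest values discarded for the trimmed
#'   maximum (default 0.05).
#' @return list: meanFd, maxFd, maxFdTrim, nOverSpike, n.
#' @export
fdSummary <- function(fd, spikeMm = 2, trimFraction = 0.05) {
  stopifnot(length(fd) >= 1L)
  nDrop <- ceiling(trimFraction * length(fd))
  trimmed <- if (nDrop >= length(fd)) numeric(0) else {
    ord <- order(fd, seq_along(fd), decreasing = TRUE)
    fd[-ord[seq_len(nDrop)]]
  }
  list(meanFd = mean(fd),
       maxFd = max(fd),
       maxFdTrim = if (length(trimmed)) max(trimmed) else 0,
       nOverSpike = sum(fd > spikeMm),
       n = length(fd))
}

#' Read / write 6-column motion-parameter traces
#'
#' Whitespace-delimited text with one row per volume: translations x, y, z
#' in mm followed by rotations in radians.
#'
#' @param path file path.
#' @return `readMotionTrace` a T x 6 matrix; the writer returns the path
#'   invisibly.
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (ncol(m) != 6L) stop("motion trace file must have 6 columns")
  m
}

#' @rdname readMotionTrace
#' @param trace T x 6 matrix.
#' @export
writeMotionTrace <- function(trace, path) {
  utils::write.table(format(trace, digits = 10), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Study-level motion QC table
#'
#' @param motion named list ("subject.condition") of T x 6 traces.
#' @param headRadiusMm,spikeMm,trimFraction passed to the FD computation.
#' @return data.frame with one row per run: run, meanFd, maxFd, maxFdTrim,
#'   nOverSpike, n.
#' @export
motionQCTable <- function(motion, headRadiusMm = 50, spikeMm = 2,
                          trimFraction = 0.05) {
  rows <- lapply(names(motion), function(nm) {
    fd <- framewiseDisplacement(motion[[nm]], headRadiusMm)
    s <- fdSummary(fd, spikeMm, trimFraction)
    data.frame(run = nm, meanFd = s$meanFd, maxFd = s$maxFd,
               maxFdTrim = s$maxFdTrim, nOverSpike = s$nOverSpike, n = s$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
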