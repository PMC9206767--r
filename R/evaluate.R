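#' @include AllClasses.R simulate.R
NULL

# Greedy one-to-one matching of detected to truth MTPs within a tolerance:
# candidate pairs are matched in order of increasing |dt| (ties: earlier
# truth first), each detected MTP usable once.
.matchMTPs <- function(detected, truth, tol = 1) {
  if (length(detected) == 0L || length(truth) == 0L)
    return(list(truthMatched = logical(length(truth)),
                detMatched = logical(length(detected))))
  pairs <- expand.grid(ti = seq_along(truth), di = seq_along(detected))
  pairs$dt <- abs(truth[pairs$ti] - detected[pairs$di])
  pairs <- pairs[pairs$dt <= tol + 1e-9, , drop = FALSE]
  pairs <- pairs[order(pairs$dt, pairs$ti), , drop = FALSE]
  tm <- logical(length(truth))
  dm <- logical(length(detected))
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs$ti[i]; di <- pairs$di[i]
    if (!tm[ti] && !dm[di]) { tm[ti] <- TRUE; dm[di] <- TRUE }
  }
  list(truthMatched = tm, detMatched = dm)
}

#' Ground-truth motion time points from a motion record
#'
#' The brain location `l_t` (mean coordinate of a reference point set) is
#' sampled at 1 Hz; the Euclidean displacement between consecutive
#' samples, `Δl_t`, is compared against a threshold in mm, and every
#' second whose displacement exceeds the threshold is a ground-truth MTP
#' (registered at the first second under the new position).
#'
#' Two inputs are supported: a high-rate position series (`positions`, an
#' N x 3 matrix at `rateHz`, resampled to 1 Hz by averaging consecutive
#' blocks), or a [MotionSchedule] plus a reference point set (default the
#' 10-cm cube vertices) from which `l_t` is computed exactly.
#'
#' @param motion a [MotionSchedule], or an N x 3 numeric matrix of
#'   positions sampled at `rateHz`.
#' @param threshold displacement threshold (mm).
#' @param duration scan length (s); required for a schedule input.
#' @param refPoints reference point set for a schedule input (rows = mm
#'   points), default [cubeVertices()].
#' @param rateHz native sampling rate of a position-series input
#'   (default 20).
#' @return numeric vector of ground-truth MTP times (s).
#' @export
groundTruthMTPs <- function(motion, threshold, duration = NULL,
                            refPoints = cubeVertices(), rateHz = 20) {
  if (is(motion, "MotionSchedule")) {
    if (is.null(duration)) stop("duration is required for a schedule input")
    secs <- 0:(floor(duration) - 1L)
    l <- t(vapply(secs, function(s)
      colMeans(applyMotion(motion, refPoints, s)), numeric(3)))
  } else {
    pos <- as.matrix(motion)
    if (nrow(pos) < 2L * rateHz) stop("position series shorter than 2 s")
    nSec <- floor(nrow(pos) / rateHz)
    grp <- rep(seq_len(nSec), each = rateHz)
    l <- rowsum(pos[seq_len(nSec * rateHz), , drop = FALSE], grp) / rateHz
    secs <- seq_len(nSec) - 1L
  }
  dl <- sqrt(rowSums((l[-1, , drop = FALSE] - l[-nrow(l), , drop = FALSE])^2))
  secs[-1][dl > threshold]
}

#' Motion detectability
#'
#' The fraction of ground-truth MTPs matched by a detected MTP within 1 s
#' before or after, under one-to-one greedy nearest matching (a single
#' detection cannot validate a burst of truth MTPs).
#'
#' @param detected numeric detected MTP times (s).
#' @param truth numeric ground-truth MTP times (s); must be nonempty.
#' @param tol match window in seconds (default 1).
#' @return fraction in `[0, 1]`.
#' @export
detectability <- function(detected, truth, tol = 1) {
  if (length(truth) == 0L) stop("detectability undefined for empty truth")
  m <- .matchMTPs(detected, truth, tol)
  mean(m$truthMatched)
}

#' False positive rate of detected MTPs
#'
#' The fraction of detected MTPs with no ground-truth MTP within the
#' match window (the detected-side complement of the one-to-one
#' matching).  An empty detection has rate 0.
#'
#' @inheritParams detectability
#' @return fraction in `[0, 1]`.
#' @export
falsePositiveRate <- function(detected, truth, tol = 1) {
  if (length(detected) == 0L) return(0)
  m <- .matchMTPs(detected, truth, tol)
  mean(!m$detMatched)
}

#' Pooled detection metrics over multiple studies
#'
#' The headline detectability is the pooled ratio: total correctly
#' detected MTPs over total ground-truth MTPs across all studies.
#' Per-study fractions are also returned.
#'
#' @param detectedList list of detected MTP time vectors, one per study.
#' @param truthList list of ground-truth MTP time vectors.
#' @param tol match window (s), default 1.
#' @return list with `pooledDetectability`, `pooledFPR`, and a per-study
#'   data.frame.
#' @export
pooledMetrics <- function(detectedList, truthList, tol = 1) {
  stopifnot(length(detectedList) == length(truthList))
  tMatch <- 0; tTruth <- 0; dUnmatch <- 0; dTot <- 0
  per <- data.frame(study = seq_along(truthList), detectability = NA_real_,
                    fpr = NA_real_)
  for (i in seq_along(truthList)) {
    m <- .matchMTPs(detectedList[[i]], truthList[[i]], tol)
    tMatch <- tMatch + sum(m$truthMatched)
    tTruth <- tTruth + length(truthList[[i]])
    dUnmatch <- dUnmatch + sum(!m$detMatched)
    dTot <- dTot + length(detectedList[[i]])
    if (length(truthList[[i]]) > 0L)
      per$detectability[i] <- mean(m$truthMatched)
    per$fpr[i] <- if (length(detectedList[[i]]) > 0L)
      mean(!m$detMatched) else 0
  }
  list(pooledDetectability = tMatch / tTruth,
       pooledFPR = if (dTot > 0) dUnmatch / dTot else 0,
       perStudy = per)
}

#' Mean distance error between two motion trajectories
#'
#' Applies the ground-truth and the estimated rigid-motion schedules to a
#' set of ROI center-of-mass points and averages, first over ROIs at each
#' sampling time and then over time, the Euclidean distance between the
#' two moved positions.
#'
#' @param roiCenters N_ROI x 3 matrix of ROI center-of-mass coordinates
#'   (mm).
#' @param gt ground-truth [MotionSchedule].
#' @param est estimated [MotionSchedule].
#' @param sampleTimes times (s) at which to evaluate; default the 1-s grid
#'   over `duration`.
#' @param duration scan length used for the default grid.
#' @return list with `mde` (mm) and `perTime` (mean ROI distance at each
#'   sample time).
#' @export
mde <- function(roiCenters, gt, est, sampleTimes = NULL, duration = NULL) {
  roiCenters <- as.matrix(roiCenters)
  stopifnot(nrow(roiCenters) >= 1L, ncol(roiCenters) == 3L)
  if (is.null(sampleTimes)) {
    if (is.null(duration)) stop("provide sampleTimes or duration")
    sampleTimes <- 0:(floor(duration) - 1L)
  }
  perTime <- vapply(sampleTimes, function(tt) {
    a <- applyMotion(gt, roiCenters, tt)
    b <- applyMotion(est, roiCenters, tt)
    mean(sqrt(rowSums((a - b)^2)))
  }, numeric(1))
  list(mde = mean(perTime), perTime = perTime)
}

#' Evaluate detections over a set of ground-truth thresholds
#'
#' @param detected numeric detected MTP times (s).
#' @param motion a [MotionSchedule] (ground truth).
#' @param duration scan length (s).
#' @param thresholds mm thresholds,
#'   default `c(0.5, 1, 2, 3, 4, 5, 6, 7, 8)`.
#' @param tol match window (s).
#' @return data.frame `threshold`, `nTruth`, `detectability`, `fpr`
#'   (detectability is `NA` where a threshold yields no truth MTPs).
#' @export
evaluateThresholds <- function(detected, motion, duration,
                               thresholds = c(0.5, 1:8), tol = 1) {
  rows <- lapply(thresholds, function(th) {
    truth <- groundTruthMTPs(motion, th, duration = duration)
    data.frame(threshold = th, nTruth = length(truth),
               detectability = if (length(truth) > 0L)
                 detectability(detected, truth, tol) else NA_real_,
               fpr = falsePositiveRate(detected, truth, tol))
  })
  do.call(rbind, rows)
}
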