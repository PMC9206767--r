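#' @include AllClasses.R
NULL

#' Number of time bins in a COD trace
#' @param x a [CODTrace].
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Per-bin event counts
#' @param x a [CODTrace].
#' @return integer vector of events per bin.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Extract one COD axis as a numeric vector
#'
#' Masked (empty) bins are returned as `NA`.
#'
#' @param x a [CODTrace].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return numeric vector of per-bin COD values (mm), `NA` where masked.
#' @export
setGeneric("codAxis", function(x, axis) standardGeneric("codAxis"))

#' Merged motion time points
#' @param x a [DetectionResult] or [Segmentation].
#' @return for a `DetectionResult`, merged MTP times in seconds; for a
#'   `Segmentation`, 1-based MTP bin indices.
#' @export
setGeneric("mtp", function(x) standardGeneric("mtp"))

#' Motion-free frames
#' @param x a [DetectionResult] or [Segmentation].
#' @return a data.frame of frame intervals.
#' @export
setGeneric("mff", function(x) standardGeneric("mff"))

#' Total within-frame residual error
#' @param x a [Segmentation].
#' @return numeric scalar E.
#' @export
setGeneric("totalError", function(x) standardGeneric("totalError"))

#' Apply a piecewise-constant rigid motion schedule to points
#'
#' @param schedule a [MotionSchedule].
#' @param points numeric 3-vector or matrix (rows = points, mm).
#' @param t time in seconds (scalar).
#' @return transformed points, same shape as `points`.
#' @export
setGeneric("applyMotion", function(schedule, points, t)
  standardGeneric("applyMotion"))

setMethod("nBins", "CODTrace", function(x) length(x@tStart))
setMethod("binCounts", "CODTrace", function(x) x@counts)
setMethod("codAxis", "CODTrace", function(x, axis) {
  axis <- match.arg(axis, c("x", "y", "z"))
  x@cod[, axis]
})
setMethod("mtp", "DetectionResult", function(x) x@mtpTimes)
setMethod("mtp", "Segmentation", function(x) x@mtps)
setMethod("mff", "DetectionResult", function(x) x@mffs)
setMethod("mff", "Segmentation", function(x) x@mffs)
setMethod("totalError", "Segmentation", function(x) x@E)

setMethod("applyMotion", "MotionSchedule", function(schedule, points, t) {
  stopifnot(length(t) == 1L, is.finite(t))
  vec <- is.null(dim(points))
  P <- if (vec) matrix(points, nrow = 1L) else as.matrix(points)
  k <- findInterval(t, schedule@times)
  if (k >= 1L) {
    R <- schedule@rotations[, , k]
    tr <- schedule@translations[, k]
    P <- P %*% t(R) + rep(tr, each = nrow(P))
  }
  if (vec) drop(P) else P
})

setMethod("show", "EventStream", function(object) {
  cat(sprintf("EventStream: %d events, mode=%s, t in [%.1f, %.1f] s\n",
              length(object@t), object@mode, min(object@t), max(object@t)))
})

setMethod("show", "CODTrace", function(object) {
  masked <- sum(object@counts == 0L)
  cat(sprintf(
    "CODTrace: %d bins of %.3g s (%.1f min), %d masked, %.3g events total\n",
    nBins(object), object@binDuration,
    nBins(object) * object@binDuration / 60, masked,
    sum(as.numeric(object@counts))))
})

setMethod("show", "MotionSchedule", function(object) {
  k <- length(object@times)
  cat(sprintf("MotionSchedule: %d step(s)\n", k))
  if (k > 0L)
    cat(sprintf("  t=%.1f s  amplitude=%.2f mm\n",
                object@times, object@amplitudes), sep = "")
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: n=%d MTPs, %d MFFs, E=%.4g\n",
              object@n, nrow(object@mffs), object@E))
})

setMethod("show", "EminCurve", function(object) {
  cat(sprintf("EminCurve: %d entries, n in [%d, %d], E_min in [%.4g, %.4g]\n",
              length(object@n), min(object@n), max(object@n),
              min(object@emin), max(object@emin)))
  cat(sprintf("  provenance: %s\n",
              paste(names(table(object@provenance)),
                    table(object@provenance), sep = ":", collapse = ", ")))
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d merged MTPs, %d MFFs\n",
              length(object@mtps), nrow(object@mffs)))
  for (ax in c("x", "y", "z")) {
    pa <- object@perAxis[[ax]]
    cat(sprintf("  %s: n_tar=%d  E_NM=%.4g  E_tar=%.4g\n",
                ax, pa$nTar, pa$enm$E_NM, pa$eTar))
  }
})
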