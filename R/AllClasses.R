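#' @import methods
NULL

#' EventStream: list-mode-like PET coincidence events
#'
#' A minimal container for list-mode-like PET events: one row per
#' coincidence, carrying the event time (seconds from scan start) and a 3D
#' localization coordinate in mm from the scanner FOV center.  In TOF mode
#' the coordinate is the center of the time-of-flight bin; in non-TOF mode
#' it is the midpoint of the line of response (LOR).
#'
#' @slot t numeric, nonnegative, nondecreasing event times (s).
#' @slot coords numeric matrix, one row per event, columns `x` (lateral),
#'   `y` (anterior-posterior), `z` (superior-inferior), mm.
#' @slot mode `"tof"` or `"nontof"`; all events share one mode.
#' @export
setClass("EventStream",
  representation(t = "numeric", coords = "matrix", mode = "character"))

setValidity("EventStream", function(object) {
  if (length(object@t) == 0L) return("event stream is empty")
  if (any(object@t < 0)) return("event times must be nonnegative")
  if (is.unsorted(object@t)) return("event times must be nondecreasing")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    return("coords must be a numeric matrix with columns x, y, z")
  if (nrow(object@coords) != length(object@t))
    return("coords and t lengths differ")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (!identical(colnames(object@coords), c("x", "y", "z")))
    return("coords columns must be named x, y, z")
  if (length(object@mode) != 1L || !object@mode %in% c("tof", "nontof"))
    return("mode must be one of 'tof', 'nontof'")
  TRUE
})

#' CODTrace: time-binned center-of-tracer-distribution trace
#'
#' The per-bin mean event coordinate (COD) in three directions, on a
#' contiguous grid of half-open bins `[t, t + binDuration)` anchored at
#' t = 0.  Bins with zero events are masked (`NA` coordinates), never
#' zero-filled: a zero would be a fake centroid.
#'
#' @slot binDuration bin width in seconds.
#' @slot tStart numeric, left edge of each bin (s).
#' @slot cod numeric matrix (bins x 3, columns `x`, `y`, `z`), per-bin mean
#'   coordinate in mm; `NA` where `counts == 0`.
#' @slot counts integer events per bin.
#' @export
setClass("CODTrace",
  representation(binDuration = "numeric", tStart = "numeric",
                 cod = "matrix", counts = "integer"))

setValidity("CODTrace", function(object) {
  nb <- length(object@tStart)
  if (length(object@binDuration) != 1L || object@binDuration <= 0)
    return("binDuration must be a positive scalar")
  if (nb == 0L) return("trace has no bins")
  if (nrow(object@cod) != nb || length(object@counts) != nb)
    return("tStart, cod, counts lengths differ")
  if (!identical(colnames(object@cod), c("x", "y", "z")))
    return("cod columns must be named x, y, z")
  d <- diff(object@tStart)
  if (nb > 1L && any(abs(d - object@binDuration) > 1e-9))
    return("bins must be contiguous and equal-duration")
  if (any(object@counts < 0L)) return("counts must be nonnegative")
  empty <- object@counts == 0L
  if (any(!is.na(object@cod[empty, , drop = FALSE])))
    return("bins with zero counts must be masked (NA)")
  if (any(is.na(object@cod[!empty, , drop = FALSE])))
    return("bins with counts > 0 must carry a COD value")
  TRUE
})

#' MotionSchedule: piecewise-constant rigid motion
#'
#' A timestamped sequence of rigid transforms.  The subject is at identity
#' before the first breakpoint; from breakpoint `k` onward the k-th
#' transform applies.  Used both as simulator ground truth and as an
#' estimated trajectory in evaluation.
#'
#' @slot times numeric breakpoints (s), strictly increasing.
#' @slot rotations 3x3xK array of rotation matrices (orthonormal).
#' @slot translations 3xK matrix of translations (mm).
#' @slot amplitudes numeric, per-step motion magnitude (mm): mean
#'   displacement of the vertices of a 10-cm cube across the step.
#' @export
setClass("MotionSchedule",
  representation(times = "numeric", rotations = "array",
                 translations = "matrix", amplitudes = "numeric"))

setValidity("MotionSchedule", function(object) {
  k <- length(object@times)
  if (k > 1L && any(diff(object@times) <= 0))
    return("breakpoints must be strictly increasing")
  if (k > 0L) {
    if (!identical(dim(object@rotations), c(3L, 3L, k)))
      return("rotations must be a 3x3xK array")
    if (!identical(dim(object@translations), c(3L, k)))
      return("translations must be a 3xK matrix")
    for (i in seq_len(k)) {
      R <- object@rotations[, , i]
      if (max(abs(crossprod(R) - diag(3))) > 1e-10)
        return("rotations must be orthonormal (R'R = I within 1e-10)")
    }
    if (length(object@amplitudes) != k)
      return("amplitudes length must match breakpoints")
  }
  TRUE
})

#' Segmentation: one changepoint scenario on a single COD axis
#'
#' An ordered set of `n` motion time points (MTPs) on the bin grid and the
#' `n + 1` motion-free frames (MFFs) they induce.  An MTP at bin index `k`
#' (1-based) is the boundary between bin `k - 1` and bin `k`.  `E` is the
#' total within-MFF residual sum of squares.
#'
#' @slot n number of changepoints.
#' @slot mtps integer bin indices (1-based, strictly increasing, interior).
#' @slot mffs data.frame: `start`, `end` (1-based bin index span, end
#'   inclusive), `N` unmasked bins, `mean`, `rss` per MFF.
#' @slot E total residual error, `sum(mffs$rss)`.
#' @export
setClass("Segmentation",
  representation(n = "integer", mtps = "integer", mffs = "data.frame",
                 E = "numeric"))

setValidity("Segmentation", function(object) {
  if (length(object@mtps) != object@n) return("n must equal length(mtps)")
  if (object@n > 1L && any(diff(object@mtps) <= 0))
    return("mtps must be strictly increasing")
  if (nrow(object@mffs) != object@n + 1L)
    return("a segmentation with n MTPs has n + 1 MFFs")
  if (any(object@mffs$rss < -1e-9)) return("per-MFF RSS must be >= 0")
  if (abs(object@E - sum(object@mffs$rss)) >
      1e-6 * max(1, abs(object@E)))
    return("E must equal the sum of per-MFF RSS")
  TRUE
})

#' EminCurve: minimum error as a function of changepoint count
#'
#' `E_min(n)` for one COD axis, with one optimizing [Segmentation] per
#' attained `n` and a provenance flag recording which engine produced each
#' value: `"exact_dp"` (segment-neighborhood DP), `"penalty_sweep"` (a
#' PELT penalty sweep, attained hull point) or `"interpolated-not-attained"`
#' (off-hull `n`, value linearly interpolated, no segmentation attached).
#'
#' @slot n integer changepoint counts (0..n_max, possibly with gaps filled
#'   by interpolated entries).
#' @slot emin numeric `E_min(n)`.
#' @slot segmentations list of [Segmentation] (or `NULL` for interpolated).
#' @slot provenance character flag per entry.
#' @export
setClass("EminCurve",
  representation(n = "integer", emin = "numeric", segmentations = "list",
                 provenance = "character"))

setValidity("EminCurve", function(object) {
  k <- length(object@n)
  if (length(object@emin) != k || length(object@provenance) != k ||
      length(object@segmentations) != k)
    return("slot lengths differ")
  if (k > 1L && any(diff(object@n) <= 0))
    return("n must be strictly increasing")
  if (k > 1L && any(diff(object@emin) > 1e-8 * max(1, object@emin[1])))
    return("E_min must be non-increasing in n")
  ok <- object@provenance %in%
    c("exact_dp", "penalty_sweep", "interpolated-not-attained")
  if (!all(ok)) return("unknown provenance flag")
  TRUE
})

#' DetectionResult: three-axis adaptive motion detection output
#'
#' Per-axis diagnostics (E_min curve, no-motion error estimate, target
#' error, selected `n_tar` and its segmentation) plus the merged
#' three-axis MTP list (sorted deduplicated union) and the merged MFFs.
#'
#' @slot perAxis named list (`x`, `y`, `z`) of per-axis results: each a
#'   list with `curve`, `enm`, `eTar`, `nTar`, `segmentation`, `warnings`.
#' @slot mtps integer merged MTP bin indices (1-based).
#' @slot mtpTimes numeric merged MTP times (s).
#' @slot mffs data.frame `start`, `end` in seconds (half-open intervals).
#' @slot config list, echo of the detection configuration.
#' @export
setClass("DetectionResult",
  representation(perAxis = "list", mtps = "integer", mtpTimes = "numeric",
                 mffs = "data.frame", config = "list"))

setValidity("DetectionResult", function(object) {
  if (!identical(names(object@perAxis), c("x", "y", "z")))
    return("perAxis must be a named list x, y, z")
  if (is.unsorted(object@mtps, strictly = TRUE) && length(object@mtps) > 1L)
    return("merged mtps must be strictly increasing")
  TRUE
})
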