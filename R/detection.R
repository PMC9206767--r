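#' @include AllClasses.R segmentation.R
NULL

#' Detection configuration
#'
#' Tunable parameters of the adaptive three-axis motion detection.
#' `alpha` is the inflation factor relating the target error level to the
#' estimated no-motion error, `E_tar = alpha * E_NM` (`alpha >= 1`);
#' calibrated defaults are 1.0 for FDG-like (spatially broad) tracer
#' distributions and 1.6 for raclopride-like (focal) distributions, and
#' 1.6 is an acceptable single choice for both.  `nMax` bounds the scouted
#' changepoint count (300 for a 90-min scan, 200 for 60 min).  `P` is the
#' number of longest motion-free frames per partition used to predict the
#' no-motion RSS.
#'
#' @param alpha inflation factor, `>= 1` (default 1.0).
#' @param nMax maximum scouted changepoint count (default 300).
#' @param partitionDuration partition length in seconds (default 300).
#' @param P longest MFFs used per partition (default 2).
#' @param binDuration COD sampling interval in seconds (default 1).
#' @param engine `"dp"` (exact, default) or `"pelt"` (penalty-sweep fast
#'   path); see [scoutEmin()].
#' @return a validated named list.
#' @export
detectionConfig <- function(alpha = 1.0, nMax = 300L,
                            partitionDuration = 300, P = 2L,
                            binDuration = 1, engine = c("dp", "pelt")) {
  engine <- match.arg(engine)
  stopifnot(alpha >= 1, nMax > 0, partitionDuration > 0, P >= 1,
            binDuration > 0)
  list(alpha = alpha, nMax = as.integer(nMax),
       partitionDuration = partitionDuration, P = as.integer(P),
       binDuration = binDuration, engine = engine)
}

#' @rdname detectionConfig
#' @details `fdgPreset()` and `racPreset()` return the calibrated defaults
#'   for a 90-min FDG-like and a 60-min raclopride-like scan.
#' @export
fdgPreset <- function() detectionConfig(alpha = 1.0, nMax = 300L)

#' @rdname detectionConfig
#' @export
racPreset <- function() detectionConfig(alpha = 1.6, nMax = 200L)

#' Estimate the no-motion error of a scan from its own COD trace
#'
#' Predicts the total RSS a hypothetical motion-free scan of the same
#' subject would produce, using the segmentation at the scouting maximum
#' `n = nMax`: within each equal-duration partition `s` the `P` longest
#' motion-free frames (or the within-partition portions of frames spanning
#' a partition edge) supply a per-sample noise estimate, scaled to the
#' partition length,
#' `RSS_NM,s = N_PART,s * sum_p(RSS_LONG,p) / sum_p(N_LONG,p)`;
#' partitioning makes the estimate adaptive to noise growth from isotope
#' decay and tracer clearance.  The scan estimate is
#' `E_NM = sum_s RSS_NM,s`.
#'
#' @param y numeric per-bin COD values for one axis (`NA` = masked).
#' @param segmentation a [Segmentation] obtained at `n = nMax`.
#' @param partitions partition table from [makePartitions()].
#' @param P number of longest frames per partition (default 2); if a
#'   partition holds fewer, all are used.
#' @return a list with `E_NM`, and `perPartition`: a data.frame of
#'   `index`, `nPart`, `rssNM`, `empty` (flag: no unmasked bins).
#' @export
estimateENM <- function(y, segmentation, partitions, P = 2L) {
  stopifnot(is(segmentation, "Segmentation"), P >= 1L)
  mffs <- segmentation@mffs
  k <- nrow(partitions)
  rssNM <- numeric(k)
  empty <- logical(k)
  for (s in seq_len(k)) {
    pa <- partitions$binStart[s]
    pb <- partitions$binEnd[s]
    # within-partition portions of overlapping MFFs
    lo <- pmax(mffs$start, pa)
    hi <- pmin(mffs$end, pb)
    sel <- which(lo <= hi)
    if (length(sel) == 0L) { empty[s] <- TRUE; next }
    stats <- lapply(sel, function(m) {
      v <- y[lo[m]:hi[m]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(NULL)
      list(N = length(v), rss = sum((v - mean(v))^2))
    })
    stats <- Filter(Negate(is.null), stats)
    if (length(stats) == 0L) { empty[s] <- TRUE; next }
    Ns <- vapply(stats, `[[`, numeric(1), "N")
    ord <- order(Ns, decreasing = TRUE)
    use <- ord[seq_len(min(P, length(ord)))]
    rssL <- vapply(stats[use], `[[`, numeric(1), "rss")
    nL <- Ns[use]
    rssNM[s] <- partitions$nPart[s] * sum(rssL) / sum(nL)
  }
  list(E_NM = sum(rssNM),
       perPartition = data.frame(index = partitions$index,
                                 nPart = partitions$nPart,
                                 rssNM = rssNM, empty = empty))
}

#' Select the target changepoint count from the E_min curve
#'
#' `n_tar` is the smallest attained `n` whose `E_min(n)` does not exceed
#' the target error level `eTar` (first crossing of the non-increasing
#' step curve).  If even `n = 0` satisfies the target, no motion is
#' detected.  If the target is below `E_min` at the scouting maximum, the
#' largest scouted `n` is returned with a warning flag (target
#' unreachable within the scouting range).
#'
#' @param curve an [EminCurve].
#' @param eTar target error level, `>= 0`.
#' @return list with `nTar`, `segmentation`, `warning` (character or NULL).
#' @export
selectNtar <- function(curve, eTar) {
  stopifnot(is(curve, "EminCurve"), eTar >= 0)
  attained <- curve@provenance != "interpolated-not-attained"
  ns <- curve@n[attained]
  es <- curve@emin[attained]
  segs <- curve@segmentations[attained]
  ok <- which(es <= eTar)
  if (length(ok) == 0L) {
    i <- length(ns)
    return(list(nTar = ns[i], segmentation = segs[[i]],
                warning = "target error level unreachable within nMax"))
  }
  i <- ok[which.min(ns[ok])]
  list(nTar = ns[i], segmentation = segs[[i]], warning = NULL)
}

#' Three-axis adaptive motion detection on a COD trace
#'
#' Runs, independently per axis: E_min scouting up to `nMax`
#' ([scoutEmin()]), no-motion error estimation from the `nMax`
#' segmentation ([estimateENM()]), target level `E_tar = alpha * E_NM`,
#' and first-crossing selection of `n_tar` ([selectNtar()]).  The final
#' detection is the sorted, deduplicated union of the three per-axis MTP
#' sets; MTPs one bin apart on different axes both survive (deduplication
#' is exact-index only).  Under the `"pelt"` engine the no-motion estimate
#' uses the attained segmentation with the largest `n <= nMax`.
#'
#' @param trace a [CODTrace].
#' @param config a [detectionConfig()] list.
#' @return a [DetectionResult].
#' @export
detect3D <- function(trace, config = detectionConfig()) {
  stopifnot(is(trace, "CODTrace"))
  parts <- makePartitions(trace, config$partitionDuration)
  perAxis <- list()
  for (ax in c("x", "y", "z")) {
    y <- codAxis(trace, ax)
    nUn <- sum(!is.na(y))
    if (nUn < 2L) stop("axis ", ax, " has fewer than 2 unmasked bins")
    nMax <- min(config$nMax, nUn - 1L)
    curve <- scoutEmin(y, nMax, engine = config$engine)
    attained <- which(curve@provenance != "interpolated-not-attained" &
                      curve@n <= nMax)
    iTop <- attained[which.max(curve@n[attained])]
    segTop <- curve@segmentations[[iTop]]
    enm <- estimateENM(y, segTop, parts, P = config$P)
    eTar <- config$alpha * enm$E_NM
    sel <- selectNtar(curve, eTar)
    perAxis[[ax]] <- list(curve = curve, enm = enm, eTar = eTar,
                          nTar = sel$nTar, segmentation = sel$segmentation,
                          warnings = sel$warning)
  }
  merged <- sort(unique(unlist(lapply(perAxis,
                                      function(p) p$segmentation@mtps))))
  merged <- as.integer(merged)
  Tn <- nBins(trace)
  bounds <- c(1L, merged, Tn + 1L)
  mffs <- data.frame(
    start = trace@tStart[bounds[-length(bounds)]],
    end = c(trace@tStart, trace@tStart[Tn] + trace@binDuration)[bounds[-1]])
  new("DetectionResult", perAxis = perAxis, mtps = merged,
      mtpTimes = trace@tStart[merged],
      mffs = mffs, config = config)
}

#' Write a detection report as JSON
#'
#' Per-axis `n_tar`, `E_NM`, `E_tar` and the E_min curve, the merged MTP
#' times (seconds), the merged MFF intervals (half-open seconds), the
#' configuration echo and any warnings.
#'
#' @param result a [DetectionResult].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDetectionReport <- function(result, path) {
  rep <- list(
    config = result@config,
    mtp_times = result@mtpTimes,
    mffs = result@mffs,
    axes = lapply(result@perAxis, function(p) list(
      n_tar = p$nTar,
      E_NM = p$enm$E_NM,
      E_tar = p$eTar,
      emin_curve = data.frame(n = p$curve@n, emin = p$curve@emin,
                              provenance = p$curve@provenance),
      warnings = if (is.null(p$warnings)) character(0) else p$warnings)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
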