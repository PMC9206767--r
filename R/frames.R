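#' @include AllClasses.R detection.R
NULL

#' Discard motion-free frames with residual intra-frame motion
#'
#' A detected frame can still contain motion (e.g. slow drift or
#' oscillation between two detected MTPs).  A frame is discarded if, on
#' any axis, the standard deviation of the COD within the frame exceeds
#' two times the predicted no-motion standard deviation of the partition
#' in which the frame resides, `2 * sqrt(RSS_NM,s / N_PART,s)` (strict
#' inequality; the partition is the one containing the frame midpoint, and
#' a frame spanning partitions uses the bin-count-weighted average of the
#' spanned partitions' predicted SDs).  Frames with fewer than 2 unmasked
#' bins have no defined SD and are kept by this rule.
#'
#' @param result a [DetectionResult] (carries the per-axis no-motion
#'   estimates and the merged frames).
#' @param trace the [CODTrace] the detection was run on.
#' @return a data.frame of frame decisions: `start`, `end` (s), `status`
#'   (`"kept"` / `"discarded_intra_motion"`), per-axis observed and
#'   predicted SD (`sd_x` .. `pred_z`, mm) and `events` (summed counts).
#' @export
pruneIntraMotion <- function(result, trace) {
  stopifnot(is(result, "DetectionResult"), is(trace, "CODTrace"))
  parts <- makePartitions(trace, result@config$partitionDuration)
  mffs <- result@mffs
  bd <- trace@binDuration
  t0 <- trace@tStart[1]
  binOf <- function(tt) pmin(pmax(as.integer(floor((tt - t0) / bd)) + 1L, 1L),
                             nBins(trace))
  k <- nrow(mffs)
  out <- data.frame(start = mffs$start, end = mffs$end,
                    status = rep("kept", k),
                    sd_x = NA_real_, sd_y = NA_real_, sd_z = NA_real_,
                    pred_x = NA_real_, pred_y = NA_real_, pred_z = NA_real_,
                    events = numeric(k))
  predSD <- lapply(result@perAxis, function(p) {
    pp <- p$enm$perPartition
    ifelse(pp$nPart > 0, sqrt(pp$rssNM / pp$nPart), 0)
  })
  for (i in seq_len(k)) {
    a <- binOf(mffs$start[i])
    b <- binOf(mffs$end[i] - bd / 2)
    out$events[i] <- sum(as.numeric(trace@counts[a:b]))
    # weighted predicted SD over spanned partitions (weights = bins inside)
    ov <- pmin(parts$binEnd, b) - pmax(parts$binStart, a) + 1L
    w <- pmax(ov, 0L)
    discard <- FALSE
    for (ax in c("x", "y", "z")) {
      v <- trace@cod[a:b, ax]
      v <- v[!is.na(v)]
      pred <- if (sum(w) > 0) sum(predSD[[ax]] * w) / sum(w) else 0
      out[[paste0("pred_", ax)]][i] <- pred
      if (length(v) >= 2L) {
        sdv <- sqrt(sum((v - mean(v))^2) / length(v))
        out[[paste0("sd_", ax)]][i] <- sdv
        if (sdv > 2 * pred) discard <- TRUE
      }
    }
    if (discard) out$status[i] <- "discarded_intra_motion"
  }
  out
}

#' Discard kept frames with too few counts
#'
#' Motion cannot be robustly estimated from frames holding too few events;
#' kept frames whose summed true-coincidence count falls below
#' `minCounts` are re-flagged `"discarded_low_count"`.  The default of two
#' million counts reflects the level at which frame registration becomes
#' reliable on clinical brain scans; scale it down for low-rate synthetic
#' data.  Statuses already assigned by the intra-motion rule are final.
#'
#' @param decisions frame-decision table from [pruneIntraMotion()].
#' @param minCounts minimum summed counts per kept frame (default 2e6).
#' @return the updated decision table.
#' @export
pruneLowCount <- function(decisions, minCounts = 2e6) {
  if (minCounts < 0) stop("minCounts must be nonnegative")
  low <- decisions$status == "kept" & decisions$events < minCounts
  decisions$status[low] <- "discarded_low_count"
  decisions
}

#' Summarise discarded scan time
#'
#' @param decisions frame-decision table.
#' @return list with `seconds` discarded, `fraction` of total frame time,
#'   and a `label` such as `"43 s (2.4%)"`.
#' @export
discardedTime <- function(decisions) {
  dur <- decisions$end - decisions$start
  disc <- sum(dur[decisions$status != "kept"])
  tot <- sum(dur)
  list(seconds = disc, fraction = disc / tot,
       label = sprintf("%.0f s (%.1f%%)", disc, 100 * disc / tot))
}

#' Write the frame gating table
#'
#' CSV `start,end,status` in seconds: the downstream reconstruction's
#' gating input (discarded frames are excluded from event-by-event
#' reconstruction).
#'
#' @param decisions frame-decision table.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGating <- function(decisions, path) {
  utils::write.csv(decisions[, c("start", "end", "status")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
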