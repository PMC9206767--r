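#' @include AllClasses.R
NULL

#' Construct an event stream
#'
#' @param t event times in seconds from scan start (nonnegative,
#'   nondecreasing).
#' @param x,y,z event localization in mm from the scanner FOV center
#'   (lateral, anterior-posterior, superior-inferior).
#' @param mode `"tof"` (coordinates are TOF-bin centers) or `"nontof"`
#'   (LOR midpoints).
#' @return an [EventStream].
#' @export
eventStream <- function(t, x, y, z, mode = c("tof", "nontof")) {
  mode <- match.arg(mode)
  coords <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  new("EventStream", t = as.numeric(t), coords = coords, mode = mode)
}

#' Construct a COD trace from per-bin values
#'
#' Low-level constructor used by [computeCOD()] and the simulator.
#'
#' @param binDuration bin width (s).
#' @param cx,cy,cz per-bin COD (mm), `NA` where the bin is empty.
#' @param counts integer events per bin.
#' @param tStart left bin edges; default a contiguous grid from 0.
#' @return a [CODTrace].
#' @export
codTrace <- function(binDuration, cx, cy, cz, counts,
                     tStart = (seq_along(cx) - 1) * binDuration) {
  cod <- cbind(x = as.numeric(cx), y = as.numeric(cy), z = as.numeric(cz))
  new("CODTrace", binDuration = binDuration, tStart = as.numeric(tStart),
      cod = cod, counts = as.integer(counts))
}

#' Compute the center-of-distribution trace from an event stream
#'
#' Events are assigned to half-open bins `[t, t + binDuration)` anchored at
#' t = 0; an event exactly on a boundary belongs to the later bin.  Each
#' bin's COD is the arithmetic mean of its event coordinates; empty bins
#' are masked (`NA`), never zero-filled.
#'
#' @param events an [EventStream].
#' @param binDuration bin width in seconds (default 1).
#' @param scanSpan total scan duration in seconds; must cover all event
#'   times.  Default: the last event time, rounded up to a whole bin.
#' @return a [CODTrace].
#' @export
computeCOD <- function(events, binDuration = 1,
                       scanSpan = ceiling(max(events@t) / binDuration) *
                         binDuration) {
  stopifnot(is(events, "EventStream"))
  if (binDuration <= 0) stop("binDuration must be positive")
  tmax <- max(events@t)
  if (scanSpan < tmax) stop("scanSpan does not cover all event times")
  nb <- max(1L, as.integer(ceiling(scanSpan / binDuration - 1e-9)))
  idx <- pmin(as.integer(floor(events@t / binDuration)) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  sums <- rowsum(events@coords, group = idx, reorder = TRUE)
  cod <- matrix(NA_real_, nrow = nb, ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  occupied <- as.integer(rownames(sums))
  cod[occupied, ] <- sums / counts[occupied]
  new("CODTrace", binDuration = binDuration,
      tStart = (seq_len(nb) - 1) * binDuration,
      cod = cod, counts = as.integer(counts))
}

#' Divide a scan into equal-duration partitions
#'
#' Partitions tile `[0, scanEnd)`.  A trailing remainder shorter than
#' `partitionDuration` is kept as its own (shorter) partition; the
#' no-motion error prediction scales by each partition's own bin count, so
#' an unequal final partition is handled naturally.
#'
#' @param trace a [CODTrace].
#' @param partitionDuration partition length in seconds (default 300);
#'   must be at least one bin.
#' @return a data.frame with columns `index`, `start`, `end` (seconds,
#'   half-open), `binStart`, `binEnd` (1-based bin index span, inclusive)
#'   and `nPart` (number of sampling intervals inside).
#' @export
makePartitions <- function(trace, partitionDuration = 300) {
  stopifnot(is(trace, "CODTrace"))
  if (partitionDuration < trace@binDuration)
    stop("partitionDuration must be at least one bin")
  scanEnd <- trace@tStart[nBins(trace)] + trace@binDuration
  nPartitions <- max(1L, as.integer(ceiling(scanEnd / partitionDuration -
                                              1e-9)))
  starts <- (seq_len(nPartitions) - 1) * partitionDuration
  ends <- pmin(starts + partitionDuration, scanEnd)
  binStart <- as.integer(floor(starts / trace@binDuration)) + 1L
  binEnd <- as.integer(ceiling(ends / trace@binDuration - 1e-9))
  data.frame(index = seq_along(starts), start = starts, end = ends,
             binStart = binStart, binEnd = binEnd,
             nPart = binEnd - binStart + 1L)
}

# ---- file formats ----------------------------------------------------------

#' Read / write event streams as columnar text
#'
#' CSV with header `t,x,y,z` and a leading comment line `# mode: tof`
#' (or `nontof`).  Gzip-compressed files are read transparently.
#'
#' @param path file path (`.csv` or `.csv.gz`).
#' @return [readEventStream()] returns an [EventStream].
#' @export
readEventStream <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  mode <- "tof"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("mode:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L) mode <- m[2]
    df <- utils::read.csv(con)
  } else {
    pushBack(first, con)
    df <- utils::read.csv(con)
  }
  eventStream(df$t, df$x, df$y, df$z, mode = mode)
}

#' @rdname readEventStream
#' @param events an [EventStream] to write.
#' @export
writeEventStream <- function(events, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# mode: %s", events@mode), con)
  utils::write.csv(
    data.frame(t = events@t, x = events@coords[, 1],
               y = events@coords[, 2], z = events@coords[, 3]),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write COD traces as CSV
#'
#' Header `t_start,cx,cy,cz,counts`; masked bins are written with empty
#' coordinate fields.
#'
#' @param path file path.
#' @return [readCODTrace()] returns a [CODTrace].
#' @export
readCODTrace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_start", "cx", "cy", "cz", "counts") %in% names(df)))
  bd <- if (nrow(df) > 1L) df$t_start[2] - df$t_start[1] else 1
  codTrace(bd, df$cx, df$cy, df$cz, df$counts, tStart = df$t_start)
}

#' @rdname readCODTrace
#' @param trace a [CODTrace] to write.
#' @export
writeCODTrace <- function(trace, path) {
  df <- data.frame(t_start = trace@tStart, cx = trace@cod[, 1],
                   cy = trace@cod[, 2], cz = trace@cod[, 3],
                   counts = trace@counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write motion schedules as CSV
#'
#' Header `t,r11,r12,r13,r21,r22,r23,r31,r32,r33,tx,ty,tz`: one row per
#' breakpoint with the row-major rotation matrix and translation (mm).
#'
#' @param path file path.
#' @return [readMotionSchedule()] returns a [MotionSchedule].
#' @export
readMotionSchedule <- function(path) {
  df <- utils::read.csv(path)
  k <- nrow(df)
  rot <- array(0, dim = c(3, 3, k))
  for (i in seq_len(k))
    rot[, , i] <- matrix(as.numeric(df[i, sprintf("r%d%d",
      rep(1:3, each = 3), rep(1:3, 3))]), 3, 3, byrow = TRUE)
  tr <- t(as.matrix(df[, c("tx", "ty", "tz")]))
  dimnames(tr) <- NULL
  sched <- new("MotionSchedule", times = df$t, rotations = rot,
               translations = tr, amplitudes = numeric(k))
  sched@amplitudes <- stepAmplitudes(sched)
  sched
}

#' @rdname readMotionSchedule
#' @param schedule a [MotionSchedule] to write.
#' @export
writeMotionSchedule <- function(schedule, path) {
  k <- length(schedule@times)
  rows <- lapply(seq_len(k), function(i) {
    R <- schedule@rotations[, , i]
    c(t = schedule@times[i],
      stats::setNames(as.numeric(t(R)),
        sprintf("r%d%d", rep(1:3, each = 3), rep(1:3, 3))),
      tx = schedule@translations[1, i], ty = schedule@translations[2, i],
      tz = schedule@translations[3, i])
  })
  utils::write.csv(as.data.frame(do.call(rbind, rows)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
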