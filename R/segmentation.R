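#' @include AllClasses.R
#' @useDynLib codmotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Masked bins (NA) never enter the changepoint cost: the engines run on the
# compressed (unmasked) values and boundaries are mapped back to the
# original bin grid.  A boundary falling inside a masked run is placed at
# the earliest equivalent index (just after the last unmasked bin on the
# left), which is also the deterministic tie-break used throughout.
.compressAxis <- function(y) {
  orig <- which(!is.na(y))
  if (length(orig) == 0L) stop("axis has no unmasked bins")
  list(values = y[orig], orig = orig, T = length(y))
}

# compressed right-segment start (1-based) -> original 1-based MTP index
.mapMTP <- function(comp, rightStart) {
  if (length(rightStart) == 0L) return(integer(0))
  comp$orig[rightStart - 1L] + 1L
}

#' Per-segment residual sum of squares
#'
#' The within-frame error of a constant-mean fit: the segment mean is the
#' average of the unmasked values and the RSS is the sum of squared
#' deviations from it (two-pass formula).  Masked (`NA`) bins are skipped
#' and do not count toward `N`.
#'
#' @param y numeric vector of per-bin COD values, `NA` = masked.
#' @param range integer range of 1-based bin indices (e.g. `3:10`);
#'   default the whole vector.
#' @return a list with `mean`, `rss` and `N` (unmasked bin count).
#' @export
segmentRSS <- function(y, range = seq_along(y)) {
  v <- y[range]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("range contains no unmasked bins")
  m <- mean(v)
  list(mean = m, rss = sum((v - m)^2), N = length(v))
}

# Build a Segmentation object from original-grid MTP indices.
.buildSegmentation <- function(y, mtps) {
  mtps <- as.integer(mtps)
  Tn <- length(y)
  bounds <- c(1L, mtps, Tn + 1L)
  k <- length(bounds) - 1L
  mffs <- data.frame(start = bounds[-length(bounds)],
                     end = bounds[-1] - 1L,
                     N = integer(k), mean = numeric(k), rss = numeric(k))
  for (i in seq_len(k)) {
    s <- segmentRSS(y, mffs$start[i]:mffs$end[i])
    mffs$N[i] <- s$N; mffs$mean[i] <- s$mean; mffs$rss[i] <- s$rss
  }
  new("Segmentation", n = length(mtps), mtps = mtps, mffs = mffs,
      E = sum(mffs$rss))
}

#' Exact minimum-error segmentation with a fixed number of changepoints
#'
#' Segment-neighborhood dynamic programming: returns the segmentation with
#' exactly `n` changepoints that globally minimizes the total within-frame
#' RSS.  Cost grows as O(n T^2), intended for traces up to a few thousand
#' bins.  Ties are broken toward the earlier boundary.
#'
#' @param y numeric per-bin COD values (`NA` = masked).
#' @param n number of changepoints; `0 <= n <` number of unmasked bins.
#' @return a [Segmentation].
#' @export
optimalSegmentation <- function(y, n) {
  comp <- .compressAxis(y)
  n <- as.integer(n)
  if (n < 0L || n >= length(comp$values))
    stop("n must satisfy 0 <= n < number of unmasked bins")
  res <- cpp_segneigh(comp$values, n)
  mtps <- .mapMTP(comp, res$cps[[n + 1L]] + 1L)
  .buildSegmentation(y, mtps)
}

#' Penalized exact changepoint detection (PELT)
#'
#' Minimizes `E + beta * n` over all segmentations, where `E` is the total
#' within-frame RSS, using Pruned Exact Linear Time dynamic programming.
#' The result is identical to un-pruned optimal partitioning.
#'
#' @param y numeric per-bin COD values (`NA` = masked).
#' @param beta penalty per changepoint, `>= 0`.
#' @return a [Segmentation] (the unpenalized `E` is in slot `E`).
#' @export
peltPenalized <- function(y, beta) {
  if (beta < 0) stop("penalty must be >= 0")
  comp <- .compressAxis(y)
  res <- cpp_pelt(comp$values, beta)
  mtps <- .mapMTP(comp, res$cps + 1L)
  .buildSegmentation(y, mtps)
}

#' Scout the minimum-error curve E_min(n)
#'
#' Computes `E_min(n)`, the minimum achievable total within-frame RSS with
#' exactly `n` changepoints, for `n = 0..nMax`, together with one
#' optimizing segmentation per attained `n`.
#'
#' Two engines are available.  `"dp"` (default) is exact segment-
#' neighborhood dynamic programming and attains every `n`.  `"pelt"` is a
#' penalty-sweep fast path: PELT is run over a shrinking set of penalties
#' (a CROPS-style interval subdivision), which attains exactly the `n` on
#' the lower convex hull of the curve; off-hull `n` are filled by linear
#' interpolation, flagged `"interpolated-not-attained"`, carry no
#' segmentation and are never used for target selection.
#'
#' @param y numeric per-bin COD values (`NA` = masked).
#' @param nMax largest `n` to scout; must be below the unmasked length.
#' @param engine `"dp"` or `"pelt"`.
#' @return an [EminCurve].
#' @export
scoutEmin <- function(y, nMax, engine = c("dp", "pelt")) {
  engine <- match.arg(engine)
  comp <- .compressAxis(y)
  nMax <- as.integer(nMax)
  if (nMax < 0L || nMax >= length(comp$values))
    stop("nMax must satisfy 0 <= nMax < number of unmasked bins")
  if (engine == "dp") {
    res <- cpp_segneigh(comp$values, nMax)
    segs <- lapply(0:nMax, function(q)
      .buildSegmentation(y, .mapMTP(comp, res$cps[[q + 1L]] + 1L)))
    emin <- vapply(segs, totalError, numeric(1))
    emin <- cummin(emin)   # guard tiny fp non-monotonicity
    return(new("EminCurve", n = 0:nMax, emin = emin,
               segmentations = segs,
               provenance = rep("exact_dp", nMax + 1L)))
  }
  .scoutEminPelt(y, comp, nMax)
}

# CROPS-style penalty sweep: collect all hull points with n <= nMax.
.scoutEminPelt <- function(y, comp, nMax) {
  runs <- new.env(parent = emptyenv())
  runPelt <- function(beta) {
    key <- sprintf("%.17g", beta)
    if (!is.null(runs[[key]])) return(runs[[key]])
    r <- cpp_pelt(comp$values, beta)
    out <- list(beta = beta, n = r$n, E = r$E, cps = r$cps)
    runs[[key]] <- out
    out
  }
  whole <- segmentRSS(comp$values)$rss
  betaHi <- whole + 1
  rHi <- runPelt(betaHi)                      # n = 0
  betaLo <- max(whole / max(1, length(comp$values)), 1e-12)
  rLo <- runPelt(betaLo)
  tries <- 0L
  while (rLo$n < nMax && betaLo > 1e-14 && tries < 60L) {
    betaLo <- betaLo / 8
    rLo <- runPelt(betaLo)
    tries <- tries + 1L
  }
  found <- list(rLo, rHi)
  stack <- list(list(lo = rLo, hi = rHi))
  guard <- 0L
  while (length(stack) > 0L && guard < 5000L) {
    guard <- guard + 1L
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (iv$lo$n <= iv$hi$n + 1L) next
    bInt <- (iv$hi$E - iv$lo$E) / (iv$lo$n - iv$hi$n)
    rInt <- runPelt(bInt)
    if (rInt$n == iv$hi$n || rInt$n == iv$lo$n) next
    found[[length(found) + 1L]] <- rInt
    stack[[length(stack) + 1L]] <- list(lo = iv$lo, hi = rInt)
    stack[[length(stack) + 1L]] <- list(lo = rInt, hi = iv$hi)
  }
  ns <- vapply(found, `[[`, integer(1), "n")
  keep <- !duplicated(ns) & ns <= nMax
  found <- found[keep]
  ns <- ns[keep]
  o <- order(ns)
  found <- found[o]
  ns <- ns[o]
  segs <- lapply(found, function(r)
    .buildSegmentation(y, .mapMTP(comp, r$cps + 1L)))
  emin <- vapply(segs, totalError, numeric(1))
  # fill off-hull n by interpolation, flagged, no segmentation attached
  allN <- ns[1]:ns[length(ns)]
  allE <- stats::approx(ns, emin, xout = allN)$y
  prov <- rep("interpolated-not-attained", length(allN))
  segAll <- vector("list", length(allN))
  at <- match(ns, allN)
  prov[at] <- "penalty_sweep"
  segAll[at] <- segs
  allE[at] <- emin
  allE <- cummin(allE)
  new("EminCurve", n = as.integer(allN), emin = allE,
      segmentations = segAll, provenance = prov)
}

#' Exhaustive-reference minimum-error curve
#'
#' Brute-force enumeration of every boundary placement, independent of the
#' dynamic-programming engines; feasible only for short traces (cost grows
#' as `choose(T - 1, n)`).  Used as a reference to validate the exact
#' engines and to freeze expected values into bundled fixtures.
#'
#' @param y numeric per-bin values (`NA` = masked).
#' @param nMax largest changepoint count to enumerate.
#' @return list with `n`, `emin`, and `mtps` (list of optimal boundary
#'   sets, original 1-based bin indices, earliest-boundary tie-break).
#' @export
bruteForceEmin <- function(y, nMax) {
  comp <- .compressAxis(y)
  Tn <- length(comp$values)
  stopifnot(nMax < Tn)
  costM <- matrix(Inf, Tn, Tn)
  for (i in seq_len(Tn)) for (j in i:Tn) {
    v <- comp$values[i:j]
    costM[i, j] <- sum((v - mean(v))^2)
  }
  emin <- numeric(nMax + 1L)
  mtps <- vector("list", nMax + 1L)
  emin[1] <- costM[1, Tn]
  mtps[[1]] <- integer(0)
  for (n in seq_len(nMax)) {
    combos <- utils::combn(Tn - 1L, n)      # boundary after compressed b
    starts <- rbind(1L, combos + 1L)
    ends <- rbind(combos, Tn)
    Es <- colSums(matrix(costM[cbind(as.vector(starts), as.vector(ends))],
                         nrow = n + 1L))
    best <- which.min(Es)                   # combn order => earliest ties
    emin[n + 1L] <- Es[best]
    mtps[[n + 1L]] <- .mapMTP(comp, combos[, best] + 1L)
  }
  list(n = 0:nMax, emin = emin, mtps = mtps)
}
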