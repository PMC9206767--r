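#' @include AllClasses.R cod-trace.R
NULL

#' Vertices of the motion-magnitude reference cube
#'
#' Head-motion magnitudes are measured as the displacement of the eight
#' vertices of a 10-cm side-length cube centered at a reference point:
#' for a step between two rigid transforms, the per-vertex displacement is
#' averaged over the eight vertices.  For a pure translation this equals
#' the translation norm; for rotations it captures the lever arm of a
#' head-sized object.
#'
#' @param center cube center (mm), default the FOV center.
#' @param side side length (mm), default 100.
#' @return an 8 x 3 matrix of vertex coordinates.
#' @export
cubeVertices <- function(center = c(0, 0, 0), side = 100) {
  g <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  as.matrix(g) * side / 2 + rep(center, each = 8)
}

#' Construct a motion schedule
#'
#' @param times breakpoint times (s), strictly increasing; the subject is
#'   at identity before the first breakpoint and under the k-th transform
#'   from `times[k]` on.
#' @param translations 3xK matrix (or K x 3, auto-transposed) of
#'   translations in mm.
#' @param rotations 3x3xK array of rotation matrices; default identity.
#' @param refPoint reference point for the amplitude metric (cube center).
#' @return a [MotionSchedule] with per-step amplitudes filled in.
#' @export
motionSchedule <- function(times, translations = NULL, rotations = NULL,
                           refPoint = c(0, 0, 0)) {
  k <- length(times)
  if (is.null(translations)) translations <- matrix(0, 3, k)
  translations <- as.matrix(translations)
  if (k > 0L && !identical(dim(translations), c(3L, k)))
    translations <- t(translations)
  dimnames(translations) <- NULL
  if (is.null(rotations)) rotations <- array(diag(3), dim = c(3, 3, k))
  sched <- new("MotionSchedule", times = as.numeric(times),
               rotations = rotations, translations = translations,
               amplitudes = numeric(k))
  sched@amplitudes <- stepAmplitudes(sched, refPoint)
  sched
}

#' Per-step motion amplitudes under the cube metric
#'
#' @param schedule a [MotionSchedule].
#' @param refPoint cube center (mm).
#' @return numeric vector, one amplitude (mm) per breakpoint.
#' @export
stepAmplitudes <- function(schedule, refPoint = c(0, 0, 0)) {
  k <- length(schedule@times)
  if (k == 0L) return(numeric(0))
  V <- cubeVertices(refPoint)
  amp <- numeric(k)
  prev <- V
  for (i in seq_len(k)) {
    cur <- V %*% t(schedule@rotations[, , i]) +
      rep(schedule@translations[, i], each = 8)
    amp[i] <- mean(sqrt(rowSums((cur - prev)^2)))
    prev <- cur
  }
  amp
}

#' Random step-wise motion schedule
#'
#' Plants `nSteps` instantaneous rigid translation steps at random
#' integer seconds (the COD sampling resolution), with a minimum
#' separation and a margin from the scan edges.  Step directions are
#' uniform on the sphere and step amplitudes (cube metric, equal to the
#' translation norm here) are uniform in `ampRange`.  Positions
#' accumulate: each step moves the head from its previous pose.
#'
#' @param nSteps number of steps.
#' @param duration scan length (s).
#' @param ampRange amplitude range in mm, default `c(2, 8)`.
#' @param minGap minimum separation between steps (s), default 120.
#' @param margin keep-out zone at the scan edges (s), default 120.
#' @param seed optional RNG seed.
#' @return a [MotionSchedule].
#' @export
randomMotionSchedule <- function(nSteps, duration, ampRange = c(2, 8),
                                 minGap = 120, margin = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  avail <- seq(margin, duration - margin)
  if (length(avail) < nSteps)
    stop("scan too short for the requested steps and margin")
  times <- NULL
  for (attempt in seq_len(5000L)) {
    cand <- sort(sample(avail, nSteps))
    if (nSteps < 2L || min(diff(cand)) >= minGap) { times <- cand; break }
  }
  if (is.null(times))
    stop("could not place ", nSteps, " steps with the requested spacing")
  amps <- stats::runif(nSteps, ampRange[1], ampRange[2])
  dirs <- matrix(stats::rnorm(3 * nSteps), nrow = 3)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  steps <- sweep(dirs, 2, amps, "*")
  U <- upper.tri(diag(nSteps), diag = TRUE) * 1   # cumulative positions
  motionSchedule(times, translations = steps %*% U)
}

#' Phantom specification for the event-level simulator
#'
#' A set of 3D Gaussian activity blobs with optional per-blob
#' mono-exponential clearance, an isotope half-life driving the global
#' count rate, and the scanner localization model (TOF blur FWHM or
#' non-TOF bore geometry).  A TOF timing resolution of `tofPs`
#' picoseconds maps to a spatial FWHM of `c * tofPs / 2` along the LOR
#' (580 ps is about 87 mm).
#'
#' @param centers K x 3 matrix of blob centers (mm).
#' @param axes K x 3 matrix of Gaussian SDs per axis (mm).
#' @param activities relative activities (nonnegative).
#' @param clearance per-blob mono-exponential clearance rate (1/s),
#'   default 0 (constant relative distribution).
#' @param halfLife isotope half-life in minutes (F-18 109.77, C-11 20.36).
#' @param rate0 initial event rate (events/s).
#' @param boreRadius scanner bore radius (mm); must exceed the phantom
#'   extent.
#' @param tofPs TOF timing resolution FWHM in picoseconds (default 580).
#' @return a validated list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(centers, axes, activities,
                        clearance = rep(0, nrow(centers)),
                        halfLife = 109.77, rate0 = 20000,
                        boreRadius = 400, tofPs = 580) {
  centers <- as.matrix(centers)
  axes <- as.matrix(axes)
  stopifnot(ncol(centers) == 3L, identical(dim(axes), dim(centers)),
            length(activities) == nrow(centers), all(activities >= 0),
            halfLife > 0, rate0 > 0)
  extent <- max(sqrt(rowSums(centers^2)) + 4 * apply(axes, 1, max))
  if (boreRadius <= extent)
    stop("bore radius must exceed the phantom extent")
  tofFwhm <- 299.792458 * tofPs * 1e-3 / 2   # c [mm/ps] * ps / 2
  structure(list(centers = centers, axes = axes,
                 activities = activities, clearance = clearance,
                 halfLife = halfLife, rate0 = rate0,
                 boreRadius = boreRadius, tofFwhm = tofFwhm),
            class = "PhantomSpec")
}

#' Simulate a list-mode-like event stream
#'
#' Event times follow an inhomogeneous Poisson process whose rate decays
#' with the isotope half-life.  Each annihilation point is drawn from the
#' (rigidly moved) activity distribution at its event time.  In TOF mode
#' the recorded coordinate is the point blurred by a Gaussian of the TOF
#' FWHM along a random direction (a TOF-bin center).  In non-TOF mode it
#' is the midpoint of the transaxial chord through the point (an LOR
#' midpoint), which halves lateral and anterior-posterior excursions in
#' expectation while preserving the axial coordinate — the attenuated but
#' detectable localization of a non-TOF scanner.  Attenuation, scatter
#' and randoms are not simulated.
#'
#' @param phantom a [phantomSpec()].
#' @param motion a [MotionSchedule] (ground truth).
#' @param duration scan length (s).
#' @param mode `"tof"` or `"nontof"`.
#' @param seed optional RNG seed; identical seed and spec reproduce the
#'   stream exactly.
#' @return an [EventStream].
#' @export
simulateEvents <- function(phantom, motion, duration,
                           mode = c("tof", "nontof"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "PhantomSpec"), is(motion, "MotionSchedule"))
  if (sum(phantom$activities) <= 0) stop("zero total activity")
  if (!is.null(seed)) set.seed(seed)
  hl <- phantom$halfLife * 60               # s
  lam <- log(2) / hl
  expN <- phantom$rate0 / lam * (1 - exp(-lam * duration))
  N <- stats::rpois(1, expN)
  if (N == 0L) stop("no events generated; raise rate0 or duration")
  u <- stats::runif(N)
  t <- sort(-log(1 - u * (1 - exp(-lam * duration))) / lam)

  # blob assignment (time-dependent weights for cleared blobs)
  K <- nrow(phantom$centers)
  if (K == 1L) {
    blob <- rep(1L, N)
  } else {
    W <- outer(rep(1, N), phantom$activities) *
      exp(-outer(t, phantom$clearance))
    cw <- t(apply(W, 1, cumsum))
    r <- stats::runif(N) * cw[, K]
    blob <- max.col(cw >= r, ties.method = "first")
  }
  P <- phantom$centers[blob, , drop = FALSE] +
    matrix(stats::rnorm(3 * N), ncol = 3) * phantom$axes[blob, , drop = FALSE]

  # apply piecewise-constant motion by schedule interval
  iv <- findInterval(t, motion@times)
  for (k in unique(iv)) {
    if (k == 0L) next
    sel <- iv == k
    P[sel, ] <- P[sel, , drop = FALSE] %*% t(motion@rotations[, , k]) +
      rep(motion@translations[, k], each = sum(sel))
  }

  if (mode == "tof") {
    d <- matrix(stats::rnorm(3 * N), ncol = 3)
    d <- d / sqrt(rowSums(d^2))
    P <- P + d * stats::rnorm(N, 0, phantom$tofFwhm / 2.3548200450309493)
  } else {
    phi <- stats::runif(N, 0, 2 * pi)
    ux <- cos(phi); uy <- sin(phi)
    proj <- P[, 1] * ux + P[, 2] * uy
    P[, 1] <- P[, 1] - proj * ux
    P[, 2] <- P[, 2] - proj * uy
  }
  eventStream(t, P[, 1], P[, 2], P[, 3], mode = mode)
}

#' Default slow tracer-distribution drift
#'
#' A smooth exponential settling of the COD baseline over the first
#' minutes of the scan, emulating tracer redistribution after injection;
#' per-axis amplitudes default to well under the smallest motion of
#' interest.
#'
#' @param amplitude length-3 per-axis asymptotic drift (mm).
#' @param tau settling time constant (s).
#' @return a function of time returning a `length(t)` x 3 matrix (mm).
#' @export
defaultDrift <- function(amplitude = c(0.6, -0.4, 0.8), tau = 900) {
  force(amplitude); force(tau)
  function(t) outer(1 - exp(-t / tau), amplitude)
}

#' Simulate a COD trace directly (statistical trace model)
#'
#' Generates a per-bin three-axis COD trace without an event stream:
#' each bin's value is `drift(t) + motion offset(t) + Gaussian noise`,
#' where the noise SD grows with isotope decay as
#' `sigma(t) = noiseSd0 * 2^(t / (2 * halfLife))` — the centroid of `n`
#' events has SD proportional to `1/sqrt(n)`, and counts halve every
#' half-life.  Per-bin counts are emitted consistently with the same
#' decay law.  The motion offset is the displacement of a reference point
#' under the schedule.
#'
#' @param duration scan length (s), default 5400 (90 min).
#' @param binDuration sampling interval (s), default 1.
#' @param noiseSd0 per-axis COD noise SD at t = 0 (mm), default 0.5.
#' @param halfLife isotope half-life in minutes, default 109.77 (F-18).
#' @param drift function of time returning a T x 3 matrix of baseline
#'   offsets (mm), default [defaultDrift()]; `NULL` for none.
#' @param motion a [MotionSchedule]; default no motion.
#' @param rate0 initial count rate (events/s) used for the per-bin counts,
#'   default 20000.
#' @param refPoint reference point whose displacement is the COD motion
#'   offset (mm), default the FOV center.
#' @param seed optional RNG seed.
#' @return list with `trace` (a [CODTrace]), `schedule`, `truthTimes`
#'   (breakpoint seconds), `offsets` (T x 3 true motion offset) and
#'   `sigma` (per-bin noise SD).
#' @export
simulateTrace <- function(duration = 5400, binDuration = 1,
                          noiseSd0 = 0.5, halfLife = 109.77,
                          drift = defaultDrift(),
                          motion = motionSchedule(numeric(0)),
                          rate0 = 20000, refPoint = c(0, 0, 0),
                          seed = NULL) {
  stopifnot(noiseSd0 >= 0, halfLife > 0)
  if (!is.null(seed)) set.seed(seed)
  tb <- seq(0, duration - binDuration / 2, by = binDuration)
  Tn <- length(tb)
  hl <- halfLife * 60
  sigma <- noiseSd0 * 2^(tb / (2 * hl))
  counts <- pmax(1L, as.integer(round(rate0 * binDuration * 2^(-tb / hl))))

  offsets <- matrix(0, Tn, 3)
  iv <- findInterval(tb, motion@times)
  for (k in unique(iv)) {
    if (k == 0L) next
    offsets[iv == k, ] <- rep(
      applyMotion(motion, refPoint, motion@times[k]) - refPoint,
      each = sum(iv == k))
  }
  base <- if (is.null(drift)) matrix(0, Tn, 3) else drift(tb)
  noise <- matrix(stats::rnorm(3 * Tn), Tn, 3) * sigma
  vals <- base + offsets + noise
  list(trace = codTrace(binDuration, vals[, 1], vals[, 2], vals[, 3],
                        counts, tStart = tb),
       schedule = motion, truthTimes = motion@times,
       offsets = offsets, sigma = sigma)
}
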