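# Independent reference implementations used as oracles.  These are
# deliberately separate from the package's engines (no shared cost code).

# RSS of a constant-mean fit, naive two-pass on a plain vector
naiveRSS <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(Inf)
  sum((v - mean(v))^2)
}

# All-segments cost matrix by direct two-pass evaluation
naiveCostMatrix <- function(y) {
  Tn <- length(y)
  M <- matrix(Inf, Tn, Tn)
  for (i in seq_len(Tn)) for (j in i:Tn) M[i, j] <- naiveRSS(y[i:j])
  M
}

# Exhaustive enumeration of E_min(n): every placement of n boundaries
enumEmin <- function(y, n, costM = naiveCostMatrix(y)) {
  Tn <- length(y)
  if (n == 0L) return(list(emin = costM[1, Tn], mtps = integer(0)))
  combos <- utils::combn(Tn - 1L, n)   # boundary after element b
  starts <- rbind(1L, combos + 1L)
  ends <- rbind(combos, Tn)
  E <- colSums(matrix(costM[cbind(as.vector(starts), as.vector(ends))],
                      nrow = n + 1L))
  best <- which.min(E)
  list(emin = E[best], mtps = combos[, best] + 1L)
}

# Un-pruned optimal partitioning for the penalized problem, O(T^2),
# vectorized over candidate split points.  Returns the penalized objective.
opPenalized <- function(y, beta) {
  Tn <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  F <- c(-beta, rep(Inf, Tn))
  for (t in seq_len(Tn)) {
    s <- seq_len(t)                     # segment y[s..t], 1-based
    n <- t - s + 1L
    S <- cs[t + 1L] - cs[s]
    S2 <- cs2[t + 1L] - cs2[s]
    cost <- pmax(S2 - S * S / n, 0)
    F[t + 1L] <- min(F[s] + cost + beta)
  }
  F[Tn + 1L]
}

# Quick simulated study used by several tests: one scan at reduced length
# with planted steps
smallStudy <- function(seed, duration = 1200, nSteps = 4,
                       noiseSd0 = 0.5) {
  sched <- randomMotionSchedule(nSteps, duration, ampRange = c(2, 8),
                                minGap = 90, margin = 60, seed = seed)
  sim <- simulateTrace(duration = duration, noiseSd0 = noiseSd0,
                       motion = sched, seed = seed + 1000L)
  list(sched = sched, sim = sim)
}
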