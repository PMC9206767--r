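---
title: "Adaptive COD-based motion detection: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive COD-based motion detection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codmotion)
```

## The model

Every PET coincidence event carries a rough 3D localization: the center
of its time-of-flight bin on a TOF scanner, or the midpoint of its line
of response without TOF. Averaging these positions over short time bins
(1 s by default) gives the center-of-tracer-distribution (COD) trace in
three directions — lateral `C_x`, anterior–posterior `C_y`,
superior–inferior `C_z`, in mm from the scanner FOV center. Because each
bin averages thousands of events, the random part of a COD bin is
Gaussian to excellent approximation (central limit theorem), with a
standard deviation that grows as counts decay, `σ ∝ 1/√counts`. Rigid
head motion shifts the underlying activity distribution, so the trace is
modeled as piecewise constant (plus slow tracer drift) with Gaussian
noise, and motion detection becomes changepoint detection under a
squared-error cost:

* For a segmentation with `n` motion time points (MTPs), each
  motion-free frame (MFF) `m` contributes
  `RSS_m = Σ_k (C_m(k) − C̄_m)²`, and the total error is
  `E = Σ_m RSS_m`.
* `E_min(n)` is the global minimum of `E` over all placements of exactly
  `n` boundaries. It is non-increasing in `n` and reaches 0 when every
  (unmasked) bin is its own frame.

The number of changepoints is *not* user-chosen. The detector estimates,
from the scan itself, what `E` would have been had the subject not moved
(`E_NM`), sets the target `E_tar = α·E_NM`, and picks the smallest `n`
with `E_min(n) ≤ E_tar`. Axes are processed independently and the final
MTP set is the sorted deduplicated union of the three per-axis sets;
MTPs one bin apart on different axes both survive (the ±1 s tolerance
belongs to evaluation, not detection).

### Estimating the no-motion error

The scan is divided into equal-duration partitions (5 min by default;
a shorter trailing remainder is kept as its own partition). Within
partition `s`, the `P` longest MFFs of the `n_max` segmentation — or the
within-partition portions of MFFs that span a partition edge — supply a
per-sample error level, scaled to the partition:

`RSS_NM,s = N_PART,s · (Σ_p RSS_LONG,p) / (Σ_p N_LONG,p)`, and
`E_NM = Σ_s RSS_NM,s`.

Partitioning is what makes the method self-adaptive: early-scan bins are
count-rich and quiet, late-scan bins are noisy, and each partition's
prediction reflects its own noise level. If a partition holds fewer than
`P` frames, all are used; a partition with no unmasked bins contributes
zero and is flagged.

Two subtleties are worth recording. First, for a frame spanning a
partition edge we use the RSS of the within-partition *portion* about
the portion's own mean (for long frames in stationary noise this agrees
in expectation with using the whole-frame per-sample ratio). Second, the
estimator is only unbiased when the frames feeding it are long: an
optimal segmentation of pure noise overfits, and the longest surviving
frames are long precisely because their data happened to be homogeneous,
so at dense scouting (`n_max` comparable to its default relative to the
trace length) `E_NM` underestimates the true no-motion error. That bias
is exactly what the inflation factor `α` absorbs — it is the package's
(and the method's) calibration knob, not a nuisance. The test suite
verifies the unbiased regime: on motion-free Gaussian traces segmented
sparsely (mean frame ≈ 100 bins), the estimate recovers `T·σ²` within
10% over 200 replicates.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `binDuration` | 1 | s | COD sampling interval |
| `alpha` | 1.0 (FDG-like), 1.6 (raclopride-like) | — | target inflation `E_tar = α·E_NM` |
| `nMax` | 300 (90-min scan), 200 (60-min) | — | scouting ceiling for `E_min(n)` |
| `partitionDuration` | 300 | s | no-motion prediction window |
| `P` | 2 | — | longest frames per partition |
| `minCounts` | 2e6 | events | low-count frame discard threshold |

`alpha` controls the sensitivity/robustness trade-off: low `α` detects
more (including spurious) MTPs and yields short frames that are harder
to register; high `α` misses small motion. Broad tracer distributions
(FDG-like) give cleaner COD traces and tolerate `α = 1.0`; focal
distributions (raclopride-like) are noisier and need `α = 1.6`; a single
`α = 1.6` is an acceptable compromise for both. `fdgPreset()` and
`racPreset()` bundle these. The per-axis `n_tar` diagnostics in a
`DetectionResult` show directly when `α` is too low (large `n_tar`,
many short frames in quiet stretches).

The low-count threshold of two million true coincidences reflects when
frame-to-reference registration becomes reliable on clinical brain
scans; synthetic data at reduced rates should scale it down (the
pipeline default is 0, i.e. off, unless configured).

## Engines and numerical choices

* **Exact engine (`"dp"`)** — segment-neighborhood dynamic programming,
  `O(n_max·T²)` in compiled code, attains every `n` in `0..n_max`. The
  default, and the reference: tests check it against exhaustive
  enumeration of all boundary placements on short traces.
* **Fast path (`"pelt"`)** — PELT solves the penalized problem
  `min E + β·n` exactly (tests check it against un-pruned optimal
  partitioning); a CROPS-style penalty-interval subdivision collects all
  penalty-attainable points, which are the lower convex hull of the
  `E_min` curve. Off-hull `n` are reported by linear interpolation and
  flagged `interpolated-not-attained`; they carry no segmentation and
  are excluded from `n_tar` selection, because the chord *under*estimates
  the true `E_min(n)` there. Under this engine the no-motion estimate
  uses the attained segmentation with the largest `n ≤ n_max` (an exact
  `n_max` hull point generally does not exist). Full 90-min scans
  (`T = 5400`, `n_max = 300`) use this engine; at that size the exact
  sweep costs minutes per axis while the penalty sweep costs seconds.
* **Costs** — segment costs come from cumulative sums of the globally
  centered trace with Kahan compensation, clamped at zero; centering
  keeps the `S2 − S²/n` cancellation harmless at mm scale. The
  user-facing `segmentRSS()` uses the literal two-pass formula. Reported
  `E` values are rebuilt in R by the two-pass formula, so a noise-free
  segmentation reports exactly 0.
* **Ties and masks** — equal-cost boundary placements resolve to the
  earlier index (determinism). Bins with zero events are masked, not
  zero-filled: a zero would be a fake centroid. Masked bins carry no
  cost, `N` counts only unmasked bins, a candidate segment with no
  unmasked bins is disallowed, and a boundary falling inside a masked
  run maps to the earliest equivalent bin.

## Frame pruning

A detected frame can still contain motion the changepoint model cannot
represent (oscillation faster than the scouting range, slow intra-frame
drift). A frame is discarded when, on any axis, its within-frame COD SD
strictly exceeds `2·sqrt(RSS_NM,s/N_PART,s)` of the partition containing
its midpoint (frames spanning partitions use the bin-count-weighted
average of the spanned predictions; frames with fewer than two unmasked
bins have no SD and pass this rule). The any-axis trigger is our
reading: motion in one direction suffices to corrupt a frame. Pruning
runs before the count rule and statuses are final, so a frame failing
both reports the intra-motion reason. Raising `α` enlarges `E_NM`
predictions and can only reduce intra-motion discards (tested).

## The simulator

Two levels, both with exact ground truth attached:

* `simulateTrace()` models the COD statistically: per-bin value =
  drift + motion offset + Gaussian noise with
  `σ(t) = σ₀·2^(t/(2·t_half))`, counts emitted consistently with the
  same decay law. Defaults are the FDG-like study conditions: 90-min
  scan, 1-s bins, `σ₀ = 0.5` mm per axis, F-18 half-life 109.77 min
  (`σ` grows ≈1.3× over the scan), smooth exponential drift settling
  within 1 mm total, and step translations at integer seconds whose
  amplitude is measured as the mean displacement of the vertices of a
  10-cm cube (for pure translations, the translation norm). The noise
  scale was fixed once to resemble published clinical COD traces and is
  configurable.
* `simulateEvents()` draws event times from an inhomogeneous Poisson
  process with decaying rate and annihilation points from moving
  Gaussian blobs. TOF mode blurs the point along a random direction by
  the TOF FWHM (580 ps ≈ 87 mm); non-TOF mode records the midpoint of a
  random transaxial chord, which halves lateral/AP excursions in
  expectation while preserving the axial coordinate — the attenuated
  localization of a non-TOF scanner, in closed form. Attenuation,
  scatter, randoms and detector normalization are not simulated, and no
  image reconstruction is attempted.

What passing tests show, and what they do not: the simulator reproduces
the *statistics* the detector relies on (Gaussian per-bin noise,
`1/√counts` scaling, step equivariance of the centroid), so the
detectability figure demonstrates the algorithm's behavior under its own
model assumptions. Real scanner data add structured effects the
simulator omits — scatter-driven baseline shifts, rate-dependent dead
time, non-rigid motion, attenuation mismatch — so simulated
detectability is an upper bound on, not a measurement of, clinical
performance.

## Evaluation conventions

Ground-truth MTPs: the reference-point trajectory is sampled at 1 Hz
(high-rate series are block-averaged), and every second whose
displacement from the previous second exceeds the threshold (0.5–8 mm
grid) is a truth MTP, registered at the first second under the new
position. A detection within 1 s before or after a truth MTP counts as
correct; matching is greedy nearest-neighbor and one-to-one, so a single
detection cannot validate a burst of truth MTPs. Detectability is
reported pooled (total matched over total truth across studies) and
per study. The false-positive rate — the unmatched fraction of detected
MTPs — is our definition on the detected side of the same matching; the
denominator is configurable in principle but fixed here. The mean
distance error applies ground-truth and estimated rigid schedules to ROI
centers-of-mass and averages the Euclidean gap first over ROIs, then
over the 1-s grid.

## Problem sizes used by the checks

The bundled checks run at sizes a laptop handles comfortably: exhaustive
enumeration oracles on traces of 10–25 bins (all `C(T−1,n)` placements),
PELT-vs-optimal-partitioning on traces up to 500 bins, estimator
calibration on 200 motion-free replicates of 600 bins, and the pooled
detectability protocol on 50 full-length 90-min three-axis traces with
the penalty-sweep engine. The same code paths scale unchanged; only the
oracles are combinatorial.

## Known limitations

* The piecewise-constant model aliases genuinely continuous motion
  (slow head roll) into staircase MTPs; the intra-frame SD rule is the
  backstop, not a fix.
* `E_NM` underestimates under dense scouting (see above); with
  `α = 1.0` the detector over-segments quiet data into short frames.
  This matches the method's design intent — sensitivity first, frame
  quality second — but users of the raw MTP list should expect
  deliberate false positives at low thresholds.
* The union across axes inherits every axis's false positives.
* Masked-bin handling assumes empty bins are rare gaps (low-count
  tails), not systematic gating.
* The CLI and file formats are text-based throughout; vendor list-mode
  parsing is out of scope (events arrive as `t,x,y,z` tables).
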