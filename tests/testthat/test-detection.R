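test_that("estimateENM is zero on noise-free piecewise-constant traces", {
  y <- rep(c(0, 5, 2), each = 100)
  tr <- codTrace(1, y, y, y, rep(100L, 300))
  seg <- optimalSegmentation(y, 2)
  parts <- makePartitions(tr, 60)
  e <- estimateENM(y, seg, parts, P = 2)
  expect_equal(e$E_NM, 0)
  expect_false(any(e$perPartition$empty))
})

test_that("a partition fully covered by one MFF recovers that MFF's RSS", {
  set.seed(20)
  y <- rnorm(100)
  tr <- codTrace(1, y, y, y, rep(10L, 100))
  seg <- optimalSegmentation(y, 0)          # single MFF covers everything
  parts <- makePartitions(tr, 100)          # one partition == the MFF
  e <- estimateENM(y, seg, parts, P = 2)
  expect_equal(e$E_NM, seg@E, tolerance = 1e-9)
})

test_that("estimateENM recovers the noise level of motion-free traces", {
  # no-motion Gaussian traces with long MFFs: the per-sample noise from
  # the longest frames, scaled to each partition, approximates T * sigma^2
  set.seed(21)
  sigma <- 1.3
  ratios <- replicate(40, {
    y <- rnorm(300, sd = sigma)
    tr <- codTrace(1, y, y, y, rep(10L, 300))
    seg <- optimalSegmentation(y, 3)
    e <- estimateENM(y, seg, makePartitions(tr, 60), P = 2)
    e$E_NM / (300 * sigma^2)
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("selectNtar picks the first crossing of the target level", {
  three <- c(rep(-2, 12), rep(3, 13), rep(0, 10))
  cv <- scoutEmin(three, 5)
  sel <- selectNtar(cv, 0)
  expect_identical(sel$nTar, 2L)            # two true steps reach E = 0
  expect_null(sel$warning)

  # target at/above E_min(0): no motion detected
  sel0 <- selectNtar(cv, cv@emin[1] + 1)
  expect_identical(sel0$nTar, 0L)

  # unreachable target on a noisy trace
  set.seed(22)
  yn <- rnorm(40)
  cvn <- scoutEmin(yn, 5)
  seln <- selectNtar(cvn, 0)
  expect_identical(seln$nTar, 5L)
  expect_match(seln$warning, "unreachable")
})

test_that("detect3D merges per-axis MTPs as a deduplicated union", {
  # identical clean step on all three axes -> one merged MTP
  s <- c(rep(0, 60), rep(6, 60))
  tr <- codTrace(1, s, s, s, rep(100L, 120))
  cfg <- detectionConfig(nMax = 10, partitionDuration = 60)
  res <- detect3D(tr, cfg)
  expect_identical(res@mtps, 61L)
  expect_equal(mtp(res), 60)                # seconds

  # disjoint steps on x and z -> union keeps both
  x <- c(rep(0, 30), rep(5, 90))
  z <- c(rep(0, 90), rep(-4, 30))
  flat <- rep(0, 120)
  tr2 <- codTrace(1, x, flat, z, rep(100L, 120))
  res2 <- detect3D(tr2, cfg)
  expect_equal(mtp(res2), c(30, 90))
  # merged MFFs tile the scan
  expect_equal(res2@mffs$start, c(0, 30, 90))
  expect_equal(res2@mffs$end, c(30, 90, 120))
})

test_that("noise-free planted steps are recovered exactly for any alpha >= 1", {
  sched <- motionSchedule(c(100, 250, 400),
                          translations = cbind(c(3, 0, 0), c(3, 2, 0),
                                               c(3, 2, -4)))
  sim <- simulateTrace(duration = 600, noiseSd0 = 0, drift = NULL,
                       motion = sched, seed = 23)
  for (alpha in c(1, 1.6, 3.2)) {
    cfg <- detectionConfig(alpha = alpha, nMax = 20,
                           partitionDuration = 120)
    res <- detect3D(sim$trace, cfg)
    expect_equal(mtp(res), c(100, 250, 400))
  }
})

test_that("detection is invariant to axis shift and consistent under scaling", {
  st <- smallStudy(seed = 24, duration = 600, nSteps = 2)
  tr <- st$sim$trace
  cfg <- detectionConfig(nMax = 30, partitionDuration = 120)
  r1 <- detect3D(tr, cfg)
  shifted <- codTrace(tr@binDuration, tr@cod[, 1] + 50, tr@cod[, 2] - 20,
                      tr@cod[, 3] + 7, tr@counts, tStart = tr@tStart)
  r2 <- detect3D(shifted, cfg)
  expect_identical(r2@mtps, r1@mtps)
  for (ax in c("x", "y", "z")) {
    expect_identical(r2@perAxis[[ax]]$nTar, r1@perAxis[[ax]]$nTar)
    expect_equal(r2@perAxis[[ax]]$enm$E_NM, r1@perAxis[[ax]]$enm$E_NM,
                 tolerance = 1e-6)
  }
  # scaling all axes by c scales E_NM and E_tar by c^2, keeps MTPs
  cc <- 2.5
  scaled <- codTrace(tr@binDuration, cc * tr@cod[, 1], cc * tr@cod[, 2],
                     cc * tr@cod[, 3], tr@counts, tStart = tr@tStart)
  r3 <- detect3D(scaled, cfg)
  expect_identical(r3@mtps, r1@mtps)
  for (ax in c("x", "y", "z"))
    expect_equal(r3@perAxis[[ax]]$eTar, cc^2 * r1@perAxis[[ax]]$eTar,
                 tolerance = 1e-6)
})

test_that("detection report JSON carries the per-axis diagnostics", {
  st <- smallStudy(seed = 25, duration = 600, nSteps = 2)
  cfg <- detectionConfig(nMax = 20, partitionDuration = 120)
  res <- detect3D(st$sim$trace, cfg)
  f <- file.path(tempdir(), "report.json")
  writeDetectionReport(res, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(as.numeric(rep$mtp_times), mtp(res))
  expect_identical(rep$axes$x$n_tar, res@perAxis$x$nTar)
  expect_equal(rep$axes$y$E_NM, res@perAxis$y$enm$E_NM)
  expect_true(all(c("n", "emin", "provenance") %in%
                  names(rep$axes$z$emin_curve)))
})
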