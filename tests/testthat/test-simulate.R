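test_that("motion schedules validate transforms and compute cube amplitudes", {
  # pure translation: amplitude equals the translation norm
  s <- motionSchedule(100, translations = c(3, 4, 0))
  expect_equal(s@amplitudes, 5)

  # rotation about z by 90 deg at the FOV center: each cube vertex moves,
  # amplitude is the mean vertex displacement (lever arm of a 10-cm cube)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  sr <- motionSchedule(50, rotations = array(Rz, c(3, 3, 1)))
  V <- cubeVertices()
  expect_equal(sr@amplitudes,
               mean(sqrt(rowSums((V %*% t(Rz) - V)^2))))

  expect_error(new("MotionSchedule", times = 10,
                   rotations = array(matrix(2, 3, 3), c(3, 3, 1)),
                   translations = matrix(0, 3, 1), amplitudes = 0),
               "orthonormal")
})

test_that("random schedules respect spacing, margins and amplitude range", {
  sched <- randomMotionSchedule(10, 5400, ampRange = c(2, 8), seed = 40)
  expect_length(sched@times, 10)
  expect_true(all(diff(sched@times) >= 120))
  expect_true(min(sched@times) >= 120 && max(sched@times) <= 5280)
  expect_true(all(sched@amplitudes >= 2 & sched@amplitudes <= 8))
})

test_that("event simulation is reproducible and decays at the half-life", {
  ph <- phantomSpec(centers = matrix(0, 1, 3),
                    axes = matrix(40, 1, 3), activities = 1,
                    halfLife = 109.77, rate0 = 500)
  noMotion <- motionSchedule(numeric(0))
  a <- simulateEvents(ph, noMotion, 600, seed = 41)
  b <- simulateEvents(ph, noMotion, 600, seed = 41)
  expect_identical(a@t, b@t)
  expect_identical(a@coords, b@coords)

  # short-half-life phantom: rate near one half-life is ~ half the initial
  phc <- phantomSpec(centers = matrix(0, 1, 3), axes = matrix(30, 1, 3),
                     activities = 1, halfLife = 5, rate0 = 3000)
  ev <- simulateEvents(phc, noMotion, 600, seed = 42)
  r0 <- sum(ev@t < 60) / 60                    # window centered at t = 30
  r1 <- sum(ev@t >= 300 - 30 & ev@t < 300 + 30) / 60   # centered at 300
  expect_lt(abs(r1 / r0 - 2^(-(300 - 30) / 300)), 0.05)
})

test_that("symmetric phantom yields zero-mean COD; steps recover in TOF COD", {
  ph <- phantomSpec(centers = matrix(0, 1, 3), axes = matrix(40, 1, 3),
                    activities = 1, rate0 = 2000)
  ev <- simulateEvents(ph, motionSchedule(numeric(0)), 600, seed = 43)
  se <- apply(ev@coords, 2, sd) / sqrt(length(ev@t))
  expect_true(all(abs(colMeans(ev@coords)) < 3 * se))

  # +2 mm x-translation from t = 300: COD mean difference recovers it
  step <- motionSchedule(300, translations = c(2, 0, 0))
  ev2 <- simulateEvents(ph, step, 600, mode = "tof", seed = 44)
  tr <- computeCOD(ev2, binDuration = 1, scanSpan = 600)
  dx <- mean(tr@cod[301:600, "x"], na.rm = TRUE) -
        mean(tr@cod[1:300, "x"], na.rm = TRUE)
  mcErr <- 3 * sd(tr@cod[, "x"], na.rm = TRUE) / sqrt(300)
  expect_lt(abs(dx - 2), mcErr + 0.3)
})

test_that("non-TOF LOR midpoints attenuate lateral steps but keep them visible", {
  ph <- phantomSpec(centers = matrix(0, 1, 3), axes = matrix(30, 1, 3),
                    activities = 1, rate0 = 4000)
  step <- motionSchedule(300, translations = c(4, 0, 0))
  evT <- simulateEvents(ph, step, 600, mode = "tof", seed = 45)
  evN <- simulateEvents(ph, step, 600, mode = "nontof", seed = 45)
  dstep <- function(ev) {
    tr <- computeCOD(ev, 1, 600)
    mean(tr@cod[301:600, "x"], na.rm = TRUE) -
      mean(tr@cod[1:300, "x"], na.rm = TRUE)
  }
  dT <- dstep(evT)
  dN <- dstep(evN)
  expect_gt(dT, 3)            # TOF recovers ~4 mm
  expect_gt(dN, 1)            # attenuated but clearly present
  expect_lt(dN, dT)           # smaller excursion than TOF
  # transaxial midpoint halves the lateral offset in expectation
  expect_lt(abs(dN - 2), 0.6)
})

test_that("trace simulator: exact steps at zero noise and closed-form sigma", {
  sched <- motionSchedule(200, translations = c(0, 0, 3))
  sim <- simulateTrace(duration = 400, noiseSd0 = 0, drift = NULL,
                       motion = sched, seed = 46)
  z <- codAxis(sim$trace, "z")
  expect_equal(z, rep(c(0, 3), c(200, 200)))
  expect_identical(sim$truthTimes, 200)

  # sigma doubles after two half-lives
  sim2 <- simulateTrace(duration = 100, noiseSd0 = 0.5, halfLife = 25 / 60,
                        drift = NULL, seed = 47)
  expect_equal(sim2$sigma[51] / sim2$sigma[1], 2, tolerance = 1e-9)

  # seeded reproducibility of the trace model
  a <- simulateTrace(duration = 300, seed = 48)
  b <- simulateTrace(duration = 300, seed = 48)
  expect_identical(a$trace@cod, b$trace@cod)
})

test_that("per-bin noise follows the decaying-counts SD law", {
  # many replicates of a short trace: empirical SD tracks sigma(t)
  reps <- 400
  hl <- 5   # minutes, fast decay so the SD growth is visible
  sims <- vapply(seq_len(reps), function(i)
    codAxis(simulateTrace(duration = 600, noiseSd0 = 0.5, halfLife = hl,
                          drift = NULL, seed = 100 + i)$trace, "x"),
    numeric(600))
  empSD <- apply(sims, 1, sd)
  expSD <- 0.5 * 2^((0:599) / (2 * hl * 60))
  # pooled ratio within 5%
  expect_lt(abs(mean(empSD / expSD) - 1), 0.05)
  expect_gt(cor(empSD, expSD), 0.9)
})
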