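#' @include detection.R frames.R simulate.R evaluate.R
NULL

.knownKeys <- list(
  top = c("seed", "out_dir", "trace", "events", "simulate", "detect",
          "prune", "evaluate", "verbosity"),
  simulate = c("kind", "duration", "bin_duration", "noise_sd0",
               "half_life", "rate0", "n_steps", "amp_range", "min_gap",
               "margin", "drift_amplitude", "drift_tau", "mode"),
  detect = c("alpha", "n_max", "partition_duration", "P", "bin_duration",
             "engine"),
  prune = c("min_counts"),
  evaluate = c("thresholds", "tol"))

.checkKeys <- function(x, where) {
  bad <- setdiff(names(x), .knownKeys[[where]])
  if (length(bad) > 0L)
    stop("unknown config key(s) under '", where, "': ",
         paste(bad, collapse = ", "))
}

#' Validate a pipeline run configuration
#'
#' Accepts a named list or a YAML file path; unknown keys are rejected
#' before any computation and the validated config is echoed verbatim
#' into every output report.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list.
#' @export
runConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  .checkKeys(config, "top")
  for (sec in c("simulate", "detect", "prune", "evaluate"))
    if (!is.null(config[[sec]])) .checkKeys(config[[sec]], sec)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$trace) && is.null(config$events) &&
      is.null(config$simulate))
    stop("config must provide one of: trace, events, simulate")
  config
}

.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 113L + stage * 7919L) %% .Machine$integer.max
}

#' Run the full detection pipeline
#'
#' Resolves the input trace (from a trace file, an event file, or the
#' simulator), runs three-axis detection, prunes frames, evaluates
#' against ground truth when available, and persists every stage artifact
#' into `outDir`: `trace.csv`, `report.json`, `gating.csv`,
#' `metrics.json` and a `provenance.json` block (config echo, seed,
#' package version).  Deterministic given the seed.
#'
#' @param config a [runConfig()] list or YAML path.
#' @param outDir output directory; default `config$out_dir` or a
#'   tempdir subdirectory.
#' @return (invisibly) a list with `trace`, `detection`, `decisions`,
#'   `metrics`, `schedule`, `outDir`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- runConfig(config)
  if (is.null(outDir))
    outDir <- if (!is.null(config$out_dir)) config$out_dir
              else file.path(tempdir(), "codmotion-run")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  schedule <- NULL

  # --- input stage ---
  tr <- tryCatch({
    if (!is.null(config$trace)) {
      readCODTrace(config$trace)
    } else if (!is.null(config$events)) {
      computeCOD(readEventStream(config$events),
                 binDuration = config$detect$bin_duration %||% 1)
    } else {
      sim <- config$simulate
      dur <- sim$duration %||% 5400
      sched <- if ((sim$n_steps %||% 0) > 0)
        randomMotionSchedule(sim$n_steps, dur,
                             ampRange = sim$amp_range %||% c(2, 8),
                             minGap = sim$min_gap %||% 120,
                             margin = sim$margin %||% 120,
                             seed = .stageSeed(config$seed, 1L))
      else motionSchedule(numeric(0))
      schedule <- sched
      st <- simulateTrace(
        duration = dur, binDuration = sim$bin_duration %||% 1,
        noiseSd0 = sim$noise_sd0 %||% 0.5,
        halfLife = sim$half_life %||% 109.77,
        drift = defaultDrift(sim$drift_amplitude %||% c(0.6, -0.4, 0.8),
                             sim$drift_tau %||% 900),
        motion = sched, rate0 = sim$rate0 %||% 20000,
        seed = .stageSeed(config$seed, 2L))
      st$trace
    }
  }, error = function(e) stop("[input] ", conditionMessage(e), call. = FALSE))
  writeCODTrace(tr, file.path(outDir, "trace.csv"))
  if (!is.null(schedule))
    writeMotionSchedule(schedule, file.path(outDir, "motion_truth.csv"))

  # --- detection stage ---
  det <- tryCatch({
    dc <- config$detect %||% list()
    cfg <- detectionConfig(alpha = dc$alpha %||% 1.0,
                           nMax = dc$n_max %||% 300L,
                           partitionDuration = dc$partition_duration %||% 300,
                           P = dc$P %||% 2L,
                           binDuration = dc$bin_duration %||% tr@binDuration,
                           engine = dc$engine %||% "dp")
    detect3D(tr, cfg)
  }, error = function(e) stop("[detect] ", conditionMessage(e), call. = FALSE))
  writeDetectionReport(det, file.path(outDir, "report.json"))

  # --- pruning stage ---
  dec <- tryCatch({
    d <- pruneIntraMotion(det, tr)
    pruneLowCount(d, minCounts = config$prune$min_counts %||% 0)
  }, error = function(e) stop("[prune] ", conditionMessage(e), call. = FALSE))
  writeGating(dec, file.path(outDir, "gating.csv"))

  # --- evaluation stage ---
  metrics <- NULL
  if (!is.null(schedule) && length(schedule@times) > 0L) {
    metrics <- tryCatch({
      ev <- config$evaluate %||% list()
      evaluateThresholds(mtp(det), schedule,
                         duration = nBins(tr) * tr@binDuration,
                         thresholds = ev$thresholds %||% c(0.5, 1:8),
                         tol = ev$tol %||% 1)
    }, error = function(e) stop("[evaluate] ", conditionMessage(e),
                                call. = FALSE))
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         dataframe = "columns", digits = NA)
  }

  prov <- list(config = config, seed = config$seed,
               version = as.character(utils::packageVersion("codmotion")),
               discarded = discardedTime(dec)$label)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(trace = tr, detection = det, decisions = dec,
                 metrics = metrics, schedule = schedule, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the canonical small test fixtures
#'
#' Generates the hand-checkable inputs used by the test suite and
#' examples: `step50` (100 bins, one clean step at bin 51, with the
#' expected MTP), `threelevel` (noise-free 3-level trace: E_min(2) = 0 <
#' E_min(1)), and `rand20` (a seeded 20-bin Gaussian trace bundled with
#' its exhaustive-enumeration E_min table from [bruteForceEmin()]).
#'
#' @param dir output directory.
#' @param seed RNG seed for `rand20`.
#' @return (invisibly) named list of written file paths.
#' @export
makeFixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  step <- c(rep(0, 50), rep(10, 50))
  tr <- codTrace(1, step, step, step, rep(1000L, 100))
  paths$step50 <- writeCODTrace(tr, file.path(dir, "step50_trace.csv"))
  writeLines("51", file.path(dir, "step50_expected_mtp.txt"))
  paths$step50_mtp <- file.path(dir, "step50_expected_mtp.txt")

  three <- c(rep(-2, 30), rep(3, 40), rep(0, 30))
  tr3 <- codTrace(1, three, three, three, rep(1000L, 100))
  paths$threelevel <- writeCODTrace(tr3, file.path(dir, "threelevel_trace.csv"))

  set.seed(seed)
  y <- stats::rnorm(20)
  tr20 <- codTrace(1, y, y, y, rep(1000L, 20))
  paths$rand20 <- writeCODTrace(tr20, file.path(dir, "rand20_trace.csv"))
  bf <- bruteForceEmin(y, 4)
  utils::write.csv(data.frame(n = bf$n, emin = bf$emin),
                   file.path(dir, "rand20_emin_table.csv"),
                   row.names = FALSE)
  paths$rand20_table <- file.path(dir, "rand20_emin_table.csv")
  invisible(paths)
}
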