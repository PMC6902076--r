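## Config-driven end-to-end orchestration: simulate -> prep -> dFNC ->
## states -> graph -> stats, with fixed seeds and a consolidated report.

#' Default run configuration
#'
#' Defaults mirror the usual resting-state dFNC conventions: TR 2 s, 10
#' initial volumes discarded from raw scans, band-pass 0.01-0.08 Hz, window
#' 20 TRs with step 1, candidate k 2..10, sparsity grid 0.01..0.50 by 0.01,
#' edgewise alpha 0.005 (uncorrected) and 0.05 elsewhere.
#'
#' @return Named list of configuration defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    tr = 2,
    discard = 0L,            # simulated cohorts are written post-discard
    band_low = 0.01,
    band_high = 0.08,
    window = 20L,
    step = 1L,
    k_min = 2L,
    k_max = 10L,
    n_init = 100L,
    max_iter = 500L,
    sparsity_min = 0.01,
    sparsity_max = 0.50,
    sparsity_step = 0.01,
    alpha_edgewise = 0.005,
    alpha = 0.05,
    trans_limit_mm = 2.0,
    rot_limit_deg = 2.0,
    cohort_dir = NULL,
    parcellation_path = NULL,
    out_dir = NULL,
    simulate = FALSE
  )
}

#' Validate a run configuration
#'
#' Merges a configuration (a named list, or a path to a YAML file) over the
#' defaults, rejects unknown keys and checks every cross-field constraint
#' that can be checked without the data (window-versus-series-length is
#' checked at run time).
#'
#' @param config named list or YAML path; `NULL` gives pure defaults.
#' @return Fully populated configuration list.
#' @export
validateConfig <- function(config = NULL) {
  defaults <- defaultRunConfig()
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config, keep.null = TRUE)

  nyquist <- 1 / (2 * cfg$tr)
  if (cfg$tr <= 0) stop("tr must be > 0")
  if (cfg$band_low <= 0) stop("band_low must be > 0")
  if (cfg$band_high <= cfg$band_low) stop("band_high must exceed band_low")
  if (cfg$band_high >= nyquist)
    stop(sprintf("band_high (%g) exceeds Nyquist %g for tr %g",
                 cfg$band_high, nyquist, cfg$tr))
  if (cfg$window < 2) stop("window must be >= 2")
  if (cfg$step < 1) stop("step must be >= 1")
  if (cfg$discard < 0) stop("discard must be >= 0")
  if (cfg$k_min < 2 || cfg$k_max < cfg$k_min) stop("need 2 <= k_min <= k_max")
  if (cfg$sparsity_min <= 0 || cfg$sparsity_max > 1 ||
      cfg$sparsity_max <= cfg$sparsity_min || cfg$sparsity_step <= 0)
    stop("invalid sparsity grid: need 0 < min < max <= 1 and step > 0")
  for (a in c("alpha_edgewise", "alpha"))
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stop(a, " must lie in (0, 1)")
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("discard", "window", "step", "k_min", "k_max",
              "n_init", "max_iter"))
    cfg[[f]] <- as.integer(cfg[[f]])
  cfg
}

#' Run the full dynamic-connectivity pipeline
#'
#' Executes all stages in order on a cohort (read from `cohort_dir`, or
#' simulated with the supplied design when `config$simulate` is `TRUE`):
#' signal conditioning with motion exclusion, static and sliding-window
#' connectivity, dFCV matrices with the edgewise covariate-adjusted group
#' test, k selection and temporal state metrics with Mann-Whitney group
#' tests, efficiency curves with AUC t tests, and the demographics table.
#' Identical config and seed give an identical report.
#'
#' @param config list from [validateConfig()] (raw lists/paths accepted).
#' @param design optional [CohortDesign-class] used when
#'   `config$simulate` is `TRUE` and no cohort directory is given.
#' @param parcellation optional [Parcellation-class]; defaults to the one
#'   implied by the cohort/simulation.
#' @param selectNInit optional smaller restart count for the k-selection
#'   sweep (defaults to `config$n_init`).
#' @return A run-report list with per-stage summaries.
#' @export
runPipeline <- function(config = NULL, design = NULL, parcellation = NULL,
                        selectNInit = NULL) {
  cfg <- validateConfig(config)
  set.seed(cfg$seed)
  warnings <- character(0)

  ## ---- stage 1: obtain cohort ------------------------------------------
  if (!is.null(cfg$cohort_dir)) {
    prep <- prepCohort(cfg$cohort_dir, trSeconds = cfg$tr,
                       discard = cfg$discard,
                       lowHz = cfg$band_low, highHz = cfg$band_high,
                       transLimitMm = cfg$trans_limit_mm,
                       rotLimitDeg = cfg$rot_limit_deg)
    manifest <- prep$manifest
    signals <- prep$signals
    exclusion <- prep$report
  } else if (isTRUE(cfg$simulate) || !is.null(design)) {
    if (is.null(design)) design <- cohortDesign(seed = cfg$seed)
    sim <- simulateCohort(design, parcellation)
    parcellation <- sim$parcellation
    manifest <- sim$manifest
    exclusion <- data.frame(subject_id = manifest$subject_id,
                            max_trans = NA_real_, max_rot = NA_real_,
                            included = TRUE)
    ## conditioning on in-memory simulated cohorts: regression + band-pass
    signals <- lapply(sim$signals, function(ts)
      prepSubject(ts, motion = NULL, trSeconds = cfg$tr, discard = cfg$discard,
                  lowHz = cfg$band_low, highHz = cfg$band_high))
  } else {
    stop("either cohort_dir or simulate/design is required")
  }
  if (length(signals) < 4L) stop("too few retained subjects to analyze")
  T <- nrow(signals[[1]])
  if (cfg$window > T)
    stop("window exceeds series length (", cfg$window, " > ", T, ")")

  ## ---- stage 2: connectivity -------------------------------------------
  W <- windowCount(T, cfg$window, cfg$step)
  wfcs <- lapply(names(signals), function(id)
    slidingFC(signals[[id]], cfg$window, cfg$step, subjectId = id))
  names(wfcs) <- names(signals)
  statics <- lapply(signals, staticFC)
  fcvs <- lapply(wfcs, computeDFCV)
  edgewise <- fcvGroupCompare(fcvs, manifest, alpha = cfg$alpha_edgewise)

  ## ---- stage 3: states --------------------------------------------------
  ks <- selectK(wfcs, kRange = cfg$k_min:cfg$k_max, seed = cfg$seed,
                nInit = if (is.null(selectNInit)) cfg$n_init else selectNInit,
                maxIter = cfg$max_iter)
  model <- ks$models[[as.character(ks$combinedK)]]
  if (is.null(model))
    model <- kmeansStates(wfcs, ks$combinedK, seed = cfg$seed,
                          nInit = cfg$n_init, maxIter = cfg$max_iter)
  metrics <- cohortStateMetrics(model)
  metricTests <- metricsGroupCompare(metrics, manifest)

  ## ---- stage 4: topology -----------------------------------------------
  grid <- seq(cfg$sparsity_min, cfg$sparsity_max, by = cfg$sparsity_step)
  curves <- lapply(names(statics), function(id) {
    z <- fisherZ(statics[[id]])
    diag(z) <- 0
    efficiencyCurve(z, grid, subjectId = id)
  })
  names(curves) <- names(statics)
  efficiencyTests <- efficiencyGroupCompare(curves, manifest)

  ## ---- stage 5: demographics -------------------------------------------
  demographics <- table1Report(manifest)

  report <- list(
    config = cfg,
    nSubjects = length(signals),
    exclusion = exclusion,
    windowCount = W,
    chosenK = ks$combinedK,
    kOptima = ks$optima,
    validity = ks$validity,
    edgewise = list(nSignificant = edgewise$nSignificant,
                    nIncreased = sum(edgewise$mask & edgewise$signMatrix > 0) / 2,
                    nDecreased = sum(edgewise$mask & edgewise$signMatrix < 0) / 2,
                    alpha = edgewise$alpha),
    stateMetrics = metrics,
    stateTests = metricTests,
    efficiencyTests = efficiencyTests,
    demographics = demographics,
    warnings = warnings
  )

  if (!is.null(cfg$out_dir)) .writeReportArtifacts(report, model, fcvs, curves,
                                                   cfg$out_dir)
  report
}

.writeReportArtifacts <- function(report, model, fcvs, curves, outDir) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  write.table(report$validity, file.path(outDir, "validity_indices.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(centroids(model), file.path(outDir, "state_centroids.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(report$stateMetrics, file.path(outDir, "state_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$stateTests, file.path(outDir, "state_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$efficiencyTests, file.path(outDir, "efficiency_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$demographics, file.path(outDir, "demographics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(windowCount = report$windowCount, chosenK = report$chosenK,
         edgewise = report$edgewise, nSubjects = report$nSubjects),
    file.path(outDir, "report_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
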