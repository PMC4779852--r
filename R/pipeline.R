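#' @include AllClasses.R
NULL

#' Assemble and validate a pipeline run configuration
#'
#' @param timeseries path to the replicate time-series file.
#' @param reactions path to the reaction-list file (or SBML when it ends
#'   in `.xml`/`.sbml`).
#' @param outputDir directory for all outputs (created if needed).
#' @param layout time-series layout, `"long"` or `"wide"`.
#' @param timeUnit input time unit (`"s"`, `"min"`, `"h"`, `"d"`).
#' @param lambda smoothing policy: a single non-negative number applied to
#'   every metabolite, or `"gcv"` for per-metabolite generalized
#'   cross-validation.
#' @param perMetaboliteLambda optional named numeric vector overriding
#'   `lambda` for specific metabolites.
#' @param gridSize omega evaluation grid length (>= 10).
#' @param epsilonRel relative denominator-masking threshold in (0, 1).
#' @param low,high strength-classification thresholds (1/s), 0 < low <
#'   high.
#' @param kappa degenerate-weight cap multiplier, see
#'   [summarizeReplicates()].
#' @param reversiblePolicy see [interactionMatrix()].
#' @param seed integer recorded with the run (the analysis itself is
#'   deterministic; the seed matters for simulated inputs).
#' @return A validated configuration (list of class `omegafluxConfig`).
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(timeseries, reactions, outputDir,
                      layout = "long", timeUnit = "s", lambda = 0,
                      perMetaboliteLambda = NULL, gridSize = 200L,
                      epsilonRel = 1e-3, low = 1e-4, high = 1e-2,
                      kappa = 10, reversiblePolicy = "both_directions",
                      seed = 1L) {
  for (p in c(timeseries, reactions))
    if (!file.exists(p)) stop("config: file not found: ", p)
  layout <- match.arg(layout, c("long", "wide"))
  timeUnit <- match.arg(timeUnit, c("s", "min", "h", "d"))
  if (!(identical(lambda, "gcv") ||
        (is.numeric(lambda) && length(lambda) == 1L && lambda >= 0)))
    stop("config: 'lambda' must be a non-negative number or \"gcv\"")
  if (!is.null(perMetaboliteLambda) &&
      (is.null(names(perMetaboliteLambda)) ||
       any(perMetaboliteLambda < 0)))
    stop("config: 'perMetaboliteLambda' must be a named non-negative vector")
  gridSize <- as.integer(gridSize)
  if (gridSize < 10L) stop("config: 'gridSize' must be at least 10")
  if (epsilonRel <= 0 || epsilonRel >= 1)
    stop("config: 'epsilonRel' must lie strictly in (0, 1)")
  if (!(low > 0 && low < high))
    stop("config: thresholds must satisfy 0 < low < high")
  structure(list(timeseries = timeseries, reactions = reactions,
                 outputDir = outputDir, layout = layout,
                 timeUnit = timeUnit, lambda = lambda,
                 perMetaboliteLambda = perMetaboliteLambda,
                 gridSize = gridSize, epsilonRel = epsilonRel,
                 low = low, high = high, kappa = kappa,
                 reversiblePolicy = reversiblePolicy,
                 seed = as.integer(seed)),
            class = "omegafluxConfig")
}

#' Read a run configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Keys match the arguments of [runConfig()];
#' `overrides` (e.g. parsed command-line flags) win over file values.
#'
#' @param path config file path.
#' @param overrides named list of values overriding the file.
#' @return A validated configuration, see [runConfig()].
#' @export
readRunConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- sub("#.*$", "", readLines(path))
  lines <- lines[trimws(lines) != ""]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*[=:]\\s*(.*)$",
                                 lines))
  if (any(vapply(m, length, integer(1)) != 3L))
    stop("malformed config line: ",
         lines[which(vapply(m, length, integer(1)) != 3L)[1]])
  vals <- stats::setNames(
    lapply(m, function(g) {
      v <- trimws(g[3])
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }),
    vapply(m, `[`, character(1), 2))
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates read -> summarize -> weighted-spline fit -> interaction
#' matrix -> omega, writing all result tables, a text report and a run
#' log into the configured output directory. Outputs are deterministic
#' for identical configuration and inputs.
#'
#' Files written: `summary.tsv` (per-point means/sds/weights),
#' `fits.tsv` (dense S, dS/dt, d2S/dt2 per metabolite),
#' `interaction_matrix.tsv`, `omega.tsv`, `omega_summary.tsv`,
#' `report.txt`, `run.log` and `config_used.txt`.
#'
#' @param config a configuration from [runConfig()] or
#'   [readRunConfig()].
#' @return Invisible list with components `series`, `fits`, `lambdas`,
#'   `network`, `N`, `Y`, `omega`, `tables` and `outputDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "omegafluxConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    logLines <<- c(logLines, line)
  }

  series <- .stage("read", readTimeseries(config$timeseries,
                                          layout = config$layout,
                                          timeUnit = config$timeUnit))
  note("read: %d metabolite series from %s", length(series),
       config$timeseries)

  series <- .stage("summarize", withCallingHandlers(
    summarizeReplicates(series, kappa = config$kappa),
    warning = function(w) {
      note("summarize warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))

  net <- .stage("network", {
    isSbml <- grepl("\\.(xml|sbml)$", config$reactions,
                    ignore.case = TRUE)
    n <- if (isSbml) readSBML(config$reactions)
         else parseReactions(config$reactions, isPath = TRUE)
    if (length(reactions(n)) == 0L)
      stop("reaction list '", config$reactions, "' contains no reactions")
    n
  })
  note("network: %d metabolites, %d reactions",
       length(metabolites(net)), length(reactions(net)))

  fitOne <- function(x) {
    lam <- config$lambda
    if (!is.null(config$perMetaboliteLambda) &&
        metaboliteId(x) %in% names(config$perMetaboliteLambda))
      lam <- config$perMetaboliteLambda[[metaboliteId(x)]]
    if (identical(lam, "gcv"))
      lam <- selectLambdaGCV(seriesTimes(x), seriesMeans(x),
                             seriesWeights(x))
    note("fit: %s lambda = %g", metaboliteId(x), lam)
    fitSmoothingSpline(seriesTimes(x), seriesMeans(x), seriesWeights(x),
                       lambda = as.numeric(lam),
                       metaboliteId = metaboliteId(x))
  }
  fits <- .stage("fit", lapply(series, fitOne))
  lambdas <- vapply(fits, splineLambda, numeric(1))

  Y <- .stage("interaction",
              interactionMatrix(net, config$reversiblePolicy))
  om <- .stage("omega", withCallingHandlers(
    omegaAllPairs(fits, Y, epsilonRel = config$epsilonRel,
                  gridSize = config$gridSize),
    warning = function(w) {
      note("omega warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  for (s in om)
    note("omega: %s->%s masked fraction %.3f", s@source, s@target,
         mean(omegaMask(s)))

  out <- function(f) file.path(config$outputDir, f)
  .stage("write", {
    writeSummary(series, out("summary.tsv"))
    fitRows <- do.call(rbind, lapply(fits, function(sp) {
      kn <- splineKnots(sp)
      g <- seq(kn[1], kn[length(kn)], length.out = config$gridSize)
      data.frame(metabolite = metaboliteId(sp), t_s = g,
                 S = evaluateSpline(sp, g, 0L),
                 dS_dt = evaluateSpline(sp, g, 1L),
                 d2S_dt2 = evaluateSpline(sp, g, 2L))
    }))
    utils::write.table(fitRows, out("fits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeInteractionMatrix(Y, out("interaction_matrix.tsv"))
    tabs <- writeOmegaTables(om, out("omega.tsv"),
                             out("omega_summary.tsv"),
                             low = config$low, high = config$high)
    rpt <- c("omegaflux pipeline report", "",
             sprintf("metabolites: %s",
                     paste(names(series), collapse = ", ")),
             sprintf("smoothing: %s", paste(
               sprintf("%s=%g", names(lambdas), lambdas),
               collapse = ", ")),
             "", "pair\tpeak_time_s\tpeak_abs_omega_per_s\tstrong_frac")
    for (s in om) {
      lab <- classifyStrength(s, config$low, config$high)
      allMasked <- all(omegaMask(s))
      rpt <- c(rpt, sprintf("%s->%s\t%s\t%s\t%.3f",
        s@source, s@target,
        if (allMasked) "NA" else format(peakTime(s)),
        if (allMasked) "NA" else
          format(max(abs(omegaValues(s)[!omegaMask(s)]))),
        mean(lab == "strong", na.rm = TRUE)))
    }
    writeLines(rpt, out("report.txt"))
    writeLines(logLines, out("run.log"))
    writeLines(c(
      sprintf("timeseries = %s", config$timeseries),
      sprintf("reactions = %s", config$reactions),
      sprintf("layout = %s", config$layout),
      sprintf("timeUnit = %s", config$timeUnit),
      sprintf("lambda = %s", paste(config$lambda, collapse = ",")),
      sprintf("gridSize = %d", config$gridSize),
      sprintf("epsilonRel = %g", config$epsilonRel),
      sprintf("low = %g", config$low),
      sprintf("high = %g", config$high),
      sprintf("seed = %d", config$seed)),
      out("config_used.txt"))
    tabs
  }) -> tables

  invisible(list(series = series, fits = fits, lambdas = lambdas,
                 network = net, N = stoichiometricMatrix(net), Y = Y,
                 omega = om, tables = tables,
                 outputDir = config$outputDir))
}

#' Generate benchmark fixture files for the pipeline
#'
#' Simulates a built-in scenario (see [benchmarkScenario()]), writes the
#' long-layout time-series file, the reaction list and a ready-to-use
#' config file into `outputDir`. The written files are exactly what
#' [runPipeline()] consumes.
#'
#' @param scenario scenario name.
#' @param outputDir output directory.
#' @param seed integer seed for the replicate noise.
#' @param cv,r optional overrides of the scenario noise plan.
#' @param lambda smoothing policy recorded in the generated config.
#' @return Invisible named list of written paths (`timeseries`,
#'   `reactions`, `config`).
#' @export
simulateCommand <- function(scenario, outputDir, seed = 1L, cv = NULL,
                            r = NULL, lambda = "gcv") {
  paths <- writeScenario(scenario, outputDir, seed = seed, cv = cv,
                         r = r)
  cfg <- file.path(outputDir, sprintf("%s_config.txt", scenario))
  writeLines(c(
    sprintf("timeseries = %s", paths$timeseries),
    sprintf("reactions = %s", paths$reactions),
    sprintf("outputDir = %s", file.path(outputDir, "results")),
    "layout = long", "timeUnit = s",
    sprintf("lambda = %s", lambda),
    sprintf("seed = %d", as.integer(seed))), cfg)
  invisible(c(paths, config = cfg))
}
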