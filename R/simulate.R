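#' @include AllClasses.R
NULL

#' Construct a mass-action kinetic model
#'
#' @param network a \linkS4class{ReactionNetwork} of irreversible
#'   reactions (write a reversible step as two lines).
#' @param rateConstants numeric vector of non-negative rate constants, one
#'   per reaction, in reaction order (or named by reaction name).
#' @param initialConcentrations named numeric vector of non-negative
#'   initial concentrations (mM); metabolites not named default to 0.
#' @return A \linkS4class{MassActionModel}.
#' @examples
#' m <- massActionModel(parseReactions("A -> B"), 0.01, c(A = 1))
#' @export
massActionModel <- function(network, rateConstants,
                            initialConcentrations = numeric(0)) {
  stopifnot(is(network, "ReactionNetwork"))
  k <- length(network@reactions)
  rnames <- vapply(network@reactions, `[[`, character(1), "name")
  if (!is.null(names(rateConstants)))
    rateConstants <- rateConstants[rnames]
  if (length(rateConstants) != k)
    stop("need one rate constant per reaction")
  if (anyNA(rateConstants) || any(rateConstants < 0))
    stop("rate constants must be non-negative")
  names(rateConstants) <- rnames
  y0 <- stats::setNames(rep(0, length(network@metabolites)),
                        network@metabolites)
  if (length(initialConcentrations)) {
    unknown <- setdiff(names(initialConcentrations), names(y0))
    if (length(unknown))
      stop("initial concentration for unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    y0[names(initialConcentrations)] <- initialConcentrations
  }
  new("MassActionModel", network = network,
      rateConstants = rateConstants, initialConcentrations = y0)
}

#' Simulate mass-action concentration trajectories
#'
#' Integrates dM/dt = N v(M) with rates
#' v_r = k_r * prod(substrate concentrations raised to their
#' stoichiometric multiplicity), using a stiff-safe solver
#' (`deSolve::lsoda`).
#'
#' @param model a \linkS4class{MassActionModel}.
#' @param times increasing numeric vector of output times (s).
#' @param rtol,atol relative and absolute integration tolerances.
#' @return Numeric matrix, metabolites x times (mM), with dimnames.
#' @export
simulateTrajectories <- function(model, times, rtol = 1e-8,
                                 atol = 1e-10) {
  stopifnot(is(model, "MassActionModel"))
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  N <- stoichiometricMatrix(model@network)
  subs <- lapply(model@network@reactions, `[[`, "substrates")
  kr <- model@rateConstants
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)          # guard tiny negative roundoff
    v <- vapply(seq_along(subs), function(r) {
      s <- subs[[r]]
      kr[r] * prod(y[s$id]^s$coef)
    }, numeric(1))
    list(drop(N %*% v))
  }
  t0 <- times[1]
  sol <- deSolve::lsoda(model@initialConcentrations, times, deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  m <- t(sol[, -1, drop = FALSE])
  colnames(m) <- NULL
  m
}

#' Draw noisy replicate measurements around simulated trajectories
#'
#' Emulates experimental replication with a constant coefficient of
#' variation: replicate k at time j for metabolite i is drawn from
#' `Normal(mean = true_ij, sd = max(cv * |true_ij|, sigmaMin))`,
#' independently, then truncated at 0 (concentrations cannot be
#' negative). The RNG state is seeded from `seed` and restored on exit,
#' so identical seeds give identical output regardless of the caller's
#' RNG state.
#'
#' @param trueValues metabolites x times matrix (mM) with row names, as
#'   from [simulateTrajectories()].
#' @param times sampling times (s), one per column.
#' @param cv coefficient of variation (fraction, >= 0).
#' @param r replicates per time point (>= 1).
#' @param seed integer seed.
#' @param sigmaMin absolute noise floor (mM) preventing zero-variance
#'   replicates at true zeros; default 1e-6.
#' @param summarize also run [summarizeReplicates()].
#' @return Named list of \linkS4class{ReplicateSeries}, one per row of
#'   `trueValues`.
#' @export
makeReplicates <- function(trueValues, times, cv, r, seed,
                           sigmaMin = 1e-6, summarize = FALSE) {
  stopifnot(cv >= 0, r >= 1, is.matrix(trueValues),
            ncol(trueValues) == length(times),
            !is.null(rownames(trueValues)))
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(as.integer(seed))
  out <- lapply(rownames(trueValues), function(id) {
    reps <- lapply(seq_along(times), function(j) {
      mu <- trueValues[id, j]
      if (cv == 0) return(rep(mu, r))
      pmax(stats::rnorm(r, mean = mu,
                        sd = max(cv * abs(mu), sigmaMin)), 0)
    })
    ReplicateSeries(id, times, reps)
  })
  names(out) <- rownames(trueValues)
  if (summarize) summarizeReplicates(out) else out
}

#' Built-in benchmark scenarios
#'
#' Returns a ready-to-run model plus sampling plan:
#' \describe{
#'   \item{decay}{the analytic validation case: a single first-order
#'     reaction A -> B with k = 0.01/s, A0 = 1 mM, sampled at 12 points
#'     over three half-lives. Its self-pair statistic recovers
#'     omega(A->A, t) = -k.}
#'   \item{chain4}{the four-metabolite, three-reaction worked chain
#'     A -> B -> C -> D.}
#'   \item{two_phase}{two independent two-step chains with a fourfold
#'     rate separation (A -> B -> C fast, D -> E -> F slow), built so the
#'     |omega| peak of the fast chain's intermediate self-pair (B -> B)
#'     precedes the slow chain's (E -> E): each intermediate's net rate
#'     changes sign when its pool turns over (at about 139 s and 555 s),
#'     |omega| spikes at the edge of the masked band around that sign
#'     change, and the sampling window keeps both rates clearly nonzero
#'     elsewhere. Mimics an early primary-metabolism response followed by
#'     a delayed secondary-metabolism response.}
#' }
#'
#' @param name scenario name.
#' @return List with elements `model` (\linkS4class{MassActionModel}),
#'   `times` (sampling times, s), `cv` (replicate coefficient of
#'   variation), `r` (replicates per point) and, for `two_phase`,
#'   `focusPairs` (list of source/target id pairs whose peak order is the
#'   scenario's designed outcome).
#' @export
benchmarkScenario <- function(name = c("decay", "chain4", "two_phase")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop("unknown scenario: ",
                                            paste(name, collapse = ", ")))
  switch(name,
    decay = {
      k <- 0.01
      list(model = massActionModel(parseReactions("A -> B"), k,
                                   c(A = 1)),
           times = seq(0, 3 * log(2) / k, length.out = 12L),
           cv = 0.05, r = 5L)
    },
    chain4 = {
      list(model = massActionModel(
             parseReactions("A -> B\nB -> C\nC -> D"),
             c(0.02, 0.01, 0.005), c(A = 1)),
           times = seq(0, 600, length.out = 12L),
           cv = 0.05, r = 5L)
    },
    two_phase = {
      net <- parseReactions("A -> B\nB -> C\nD -> E\nE -> F")
      list(model = massActionModel(net,
             c(0.01, 0.005, 0.0025, 0.00125), c(A = 1, D = 1)),
           times = seq(0, 700, length.out = 24L),
           cv = 0.05, r = 5L,
           focusPairs = list(c("B", "B"), c("E", "E")))
    })
}

#' Write a scenario to time-series and reaction-list files
#'
#' Simulates the scenario model, draws noisy replicates, and writes a
#' long-layout time-series file plus the plain-text reaction list — the
#' same formats [readTimeseries()] and [parseReactions()] consume. This
#' is the packaged stand-in for experimental datasets.
#'
#' @param scenario scenario name, see [benchmarkScenario()].
#' @param dir output directory (created if needed).
#' @param seed integer seed for the replicate noise.
#' @param cv,r optional overrides of the scenario's noise plan.
#' @return Named list of written paths (`timeseries`, `reactions`),
#'   invisibly.
#' @export
writeScenario <- function(scenario, dir, seed, cv = NULL, r = NULL) {
  sc <- benchmarkScenario(scenario)
  if (!is.null(cv)) sc$cv <- cv
  if (!is.null(r)) sc$r <- r
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulateTrajectories(sc$model, sc$times)
  series <- makeReplicates(traj, sc$times, sc$cv, sc$r, seed = seed)
  tsPath <- file.path(dir, sprintf("%s_timeseries.tsv", scenario))
  writeTimeseries(series, tsPath, layout = "long")
  rxPath <- file.path(dir, sprintf("%s_reactions.txt", scenario))
  writeLines(vapply(sc$model@network@reactions, function(rx) {
    side <- function(s) paste(
      ifelse(s$coef == 1, s$id, sprintf("%g %s", s$coef, s$id)),
      collapse = " + ")
    sprintf("%s: %s %s %s", rx$name, side(rx$substrates),
            if (rx$reversible) "<->" else "->", side(rx$products))
  }, character(1)), rxPath)
  invisible(list(timeseries = tsPath, reactions = rxPath))
}
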