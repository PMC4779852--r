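#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- ##
## ReplicateSeries                                                   ##
## ---------------------------------------------------------------- ##

#' Replicate metabolite time series
#'
#' Holds one metabolite's replicate concentration measurements over an
#' ordered set of time points, together with (once computed) per-time-point
#' means, sample standard deviations and inverse-variance weights.
#' Concentrations are in mM, times in seconds, weights in mM^-2.
#'
#' @slot metaboliteId character scalar.
#' @slot times strictly increasing numeric vector of z >= 2 times (s).
#' @slot replicates list of z numeric vectors, each with r_j >= 1
#'   concentration values (mM); replicate counts may differ across points.
#' @slot means,sds,weights numeric vectors of length z once
#'   [summarizeReplicates()] has run, otherwise length 0. `sds` is `NA`
#'   where r_j < 2; `weights` are always finite and strictly positive.
#'
#' @seealso [ReplicateSeries()], [summarizeReplicates()], [readTimeseries()]
#' @export
setClass("ReplicateSeries",
  slots = c(metaboliteId = "character",
            times        = "numeric",
            replicates   = "list",
            means        = "numeric",
            sds          = "numeric",
            weights      = "numeric"))

setValidity("ReplicateSeries", function(object) {
  msg <- character()
  z <- length(object@times)
  if (length(object@metaboliteId) != 1L || is.na(object@metaboliteId))
    msg <- c(msg, "'metaboliteId' must be a single non-NA string")
  if (z < 2L)
    msg <- c(msg, "at least 2 distinct time points are required")
  if (anyNA(object@times) || is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be strictly increasing with no duplicates")
  if (length(object@replicates) != z)
    msg <- c(msg, "'replicates' must have one vector per time point")
  else {
    nrep <- vapply(object@replicates, length, integer(1))
    if (any(nrep < 1L))
      msg <- c(msg, "every time point needs at least one replicate value")
    if (any(vapply(object@replicates, anyNA, logical(1))))
      msg <- c(msg, "replicate vectors must not contain NA (drop them first)")
  }
  for (s in c("means", "sds", "weights")) {
    v <- slot(object, s)
    if (length(v) != 0L && length(v) != z)
      msg <- c(msg, sprintf("'%s' must be empty or of length z", s))
  }
  if (length(object@weights) &&
      (anyNA(object@weights) || any(!is.finite(object@weights)) ||
       any(object@weights <= 0)))
    msg <- c(msg, "'weights' must be finite and strictly positive")
  if (length(object@means) == z && length(object@replicates) == z) {
    m <- vapply(object@replicates, mean, numeric(1))
    sc <- max(abs(m), 1)
    if (max(abs(m - object@means)) > 1e-8 * sc)
      msg <- c(msg, "'means' disagree with the arithmetic replicate means")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReplicateSeries
#'
#' @param metaboliteId character scalar identifier.
#' @param times numeric vector of time points; converted to seconds via
#'   `timeUnit`.
#' @param replicates list of numeric vectors (one per time point), or a
#'   matrix with one column per time point.
#' @param timeUnit one of `"s"`, `"min"`, `"h"`, `"d"`.
#' @param summarize logical; also compute means/sds/weights.
#' @param ... passed to [summarizeReplicates()] when `summarize = TRUE`.
#' @return A \linkS4class{ReplicateSeries}.
#' @examples
#' rs <- ReplicateSeries("Suc", times = c(0, 60, 120),
#'                       replicates = list(c(1, 1.1), c(2, 2.2), c(1.5, 1.4)))
#' seriesMeans(summarizeReplicates(rs))
#' @export
ReplicateSeries <- function(metaboliteId, times, replicates,
                            timeUnit = "s", summarize = FALSE, ...) {
  if (is.matrix(replicates))
    replicates <- lapply(seq_len(ncol(replicates)), function(j)
      replicates[, j][!is.na(replicates[, j])])
  replicates <- lapply(replicates, function(v) as.numeric(v[!is.na(v)]))
  keep <- vapply(replicates, length, integer(1)) > 0L
  if (!all(keep)) {
    warning(sprintf("%s: dropping %d time point(s) with no usable replicates",
                    metaboliteId, sum(!keep)))
    times <- times[keep]; replicates <- replicates[keep]
  }
  obj <- new("ReplicateSeries",
             metaboliteId = as.character(metaboliteId),
             times = toSeconds(as.numeric(times), timeUnit),
             replicates = replicates,
             means = numeric(0), sds = numeric(0), weights = numeric(0))
  if (summarize) summarizeReplicates(obj, ...) else obj
}

## ---------------------------------------------------------------- ##
## SmoothingSpline                                                   ##
## ---------------------------------------------------------------- ##

#' Inverse variance-weighted cubic smoothing spline
#'
#' A natural cubic spline with knots at the data times, fitted by
#' minimising the penalised weighted least-squares objective
#' `sum_j w_j [y_j - S(t_j)]^2 + lambda * Int S''(t)^2 dt`.
#' Each subinterval `[t_j, t_(j+1)]` carries a cubic piece
#' `alpha + beta*u + gamma*u^2 + delta*u^3`, `u = t - t_j`; the pieces join
#' with continuous value, first and second derivative, and the second
#' derivative vanishes at both boundary knots (natural spline).
#'
#' @slot metaboliteId character scalar (may be `NA`).
#' @slot knots numeric vector of z node times (s), strictly increasing.
#' @slot coefficients `(z-1) x 4` matrix, columns
#'   `alpha, beta, gamma, delta`.
#' @slot lambda non-negative smoothing factor; 0 interpolates the nodes,
#'   `Inf`-like values approach the weighted least-squares line.
#'
#' @seealso [fitSmoothingSpline()], [evaluateSpline()], [splineObjective()]
#' @export
setClass("SmoothingSpline",
  slots = c(metaboliteId = "character",
            knots        = "numeric",
            coefficients = "matrix",
            lambda       = "numeric"))

setValidity("SmoothingSpline", function(object) {
  msg <- character()
  z <- length(object@knots)
  if (z < 2L || is.unsorted(object@knots, strictly = TRUE))
    msg <- c(msg, "'knots' must be >= 2 strictly increasing times")
  if (!identical(dim(object@coefficients), c(z - 1L, 4L)))
    msg <- c(msg, "'coefficients' must be a (z-1) x 4 matrix")
  if (length(object@lambda) != 1L || is.na(object@lambda) ||
      object@lambda < 0)
    msg <- c(msg, "'lambda' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------- ##
## ReactionNetwork                                                   ##
## ---------------------------------------------------------------- ##

#' Biochemical reaction network
#'
#' An ordered metabolite list plus a list of reactions. Each reaction is a
#' list with elements `name`, `substrates` and `products` (data.frames with
#' columns `id`, `coef`), `reversible` (logical) and `effectors` (data.frame
#' with columns `id`, `role`; roles are `"inhibitor"`, `"activator"` or
#' `"modifier"`).
#'
#' @slot metabolites character vector of n unique ids, first-appearance
#'   order.
#' @slot reactions list of k reaction records as described above.
#'
#' @seealso [parseReactions()], [readSBML()], [stoichiometricMatrix()],
#'   [interactionMatrix()]
#' @export
setClass("ReactionNetwork",
  slots = c(metabolites = "character", reactions = "list"))

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@metabolites))
    msg <- c(msg, "metabolite ids must be unique")
  for (i in seq_along(object@reactions)) {
    r <- object@reactions[[i]]
    need <- c("name", "substrates", "products", "reversible", "effectors")
    if (!all(need %in% names(r))) {
      msg <- c(msg, sprintf("reaction %d lacks required fields", i))
      next
    }
    ids <- c(r$substrates$id, r$products$id, r$effectors$id)
    if (!all(ids %in% object@metabolites))
      msg <- c(msg, sprintf(
        "reaction %d references unknown metabolite(s): %s", i,
        paste(setdiff(ids, object@metabolites), collapse = ", ")))
    coefs <- c(r$substrates$coef, r$products$coef)
    if (length(coefs) && any(!is.finite(coefs) | coefs <= 0))
      msg <- c(msg, sprintf(
        "reaction %d has non-positive stoichiometric coefficients", i))
    if (nrow(r$effectors) &&
        !all(r$effectors$role %in% c("inhibitor", "activator", "modifier")))
      msg <- c(msg, sprintf("reaction %d has an unknown effector role", i))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------- ##
## InteractionMatrix                                                 ##
## ---------------------------------------------------------------- ##

#' Binary metabolic interaction matrix
#'
#' An `n x n` 0/1 matrix derived from network stoichiometry. Rows index
#' metabolic functions (net rates of change of each metabolite), columns
#' index metabolites; entry (i, j) = 1 states that the metabolic function
#' of metabolite i biochemically depends on the concentration of
#' metabolite j (j is a substrate or annotated effector of a reaction that
#' changes i). Diagonal ones mark dependence of a function on its own
#' pool's concentration.
#'
#' @slot entries integer `n x n` matrix of 0/1 with metabolite dimnames.
#'
#' @seealso [interactionMatrix()], [omegaAllPairs()]
#' @export
setClass("InteractionMatrix", slots = c(entries = "matrix"))

setValidity("InteractionMatrix", function(object) {
  e <- object@entries
  msg <- character()
  if (nrow(e) != ncol(e))
    msg <- c(msg, "'entries' must be square")
  if (!all(e %in% c(0L, 1L)))
    msg <- c(msg, "'entries' must contain only 0 and 1")
  if (nrow(e) > 0L &&
      (is.null(rownames(e)) || is.null(colnames(e)) ||
       !identical(rownames(e), colnames(e))))
    msg <- c(msg, "row and column names must both give the metabolite order")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------- ##
## OmegaSeries                                                       ##
## ---------------------------------------------------------------- ##

#' Time-resolved interaction-ratio series omega(a->b, t)
#'
#' The ratio of the second time derivative of the smoothed concentration of
#' a target metabolite b to the first time derivative (the metabolic
#' function f_a) of a source metabolite a, evaluated on a time grid. Units
#' are 1/s (mM s^-2 over mM s^-1). Grid points where `|f_a|` falls at or
#' below the masking threshold approximate the excluded domain on which the
#' ratio is undefined; values there are `NA` and flagged in `mask`.
#'
#' @slot source,target metabolite ids a (denominator) and b (numerator).
#' @slot grid evaluation times (s).
#' @slot values omega values (1/s); finite wherever `mask` is `FALSE`.
#' @slot mask logical; `TRUE` where `|f_a| <= epsilon`.
#' @slot epsilon absolute masking threshold on `|f_a|` (mM/s) actually
#'   applied (derived from the relative threshold and `max |f_a|`).
#'
#' @seealso [omegaSeries()], [absOmega()], [peakTime()],
#'   [classifyStrength()]
#' @export
setClass("OmegaSeries",
  slots = c(source = "character", target = "character",
            grid = "numeric", values = "numeric",
            mask = "logical", epsilon = "numeric"))

setValidity("OmegaSeries", function(object) {
  msg <- character()
  n <- length(object@grid)
  if (length(object@values) != n || length(object@mask) != n)
    msg <- c(msg, "'values' and 'mask' must match the grid length")
  if (any(!is.finite(object@values[!object@mask])))
    msg <- c(msg, "values must be finite wherever unmasked")
  if (length(object@epsilon) != 1L || object@epsilon < 0)
    msg <- c(msg, "'epsilon' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------- ##
## MassActionModel                                                   ##
## ---------------------------------------------------------------- ##

#' Mass-action kinetic model for synthetic data
#'
#' A reaction network with per-reaction rate constants and initial
#' concentrations, defining the ODE system dM/dt = N v(M) with rates
#' v_r = k_r * prod(substrate concentrations, with multiplicity).
#'
#' @slot network a \linkS4class{ReactionNetwork} of irreversible reactions.
#' @slot rateConstants named non-negative numeric vector, one per reaction
#'   (1/s for first-order steps).
#' @slot initialConcentrations named non-negative numeric vector, one per
#'   metabolite (mM).
#'
#' @seealso [massActionModel()], [simulateTrajectories()],
#'   [benchmarkScenario()]
#' @export
setClass("MassActionModel",
  slots = c(network = "ReactionNetwork",
            rateConstants = "numeric",
            initialConcentrations = "numeric"))

setValidity("MassActionModel", function(object) {
  msg <- character()
  k <- length(object@network@reactions)
  if (length(object@rateConstants) != k)
    msg <- c(msg, "one rate constant per reaction is required")
  if (any(object@rateConstants < 0) || anyNA(object@rateConstants))
    msg <- c(msg, "rate constants must be non-negative")
  if (any(vapply(object@network@reactions, `[[`, logical(1), "reversible")))
    msg <- c(msg, paste("reversible reactions are not supported by the",
                        "mass-action simulator; write the two directions",
                        "as separate reactions"))
  n <- object@network@metabolites
  if (!identical(sort(names(object@initialConcentrations)), sort(n)))
    msg <- c(msg, "initial concentrations must name every metabolite")
  if (any(object@initialConcentrations < 0))
    msg <- c(msg, "initial concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------- ##
## show methods                                                      ##
## ---------------------------------------------------------------- ##

setMethod("show", "ReplicateSeries", function(object) {
  z <- length(object@times)
  r <- range(vapply(object@replicates, length, integer(1)))
  cat(sprintf("ReplicateSeries '%s': %d time points over [%g, %g] s, %s\n",
              object@metaboliteId, z, object@times[1], object@times[z],
              if (r[1] == r[2]) sprintf("r = %d replicates", r[1])
              else sprintf("r = %d..%d replicates", r[1], r[2])))
  cat(if (length(object@weights)) "  summarized (means/sds/weights set)\n"
      else "  not yet summarized\n")
})

setMethod("show", "SmoothingSpline", function(object) {
  z <- length(object@knots)
  cat(sprintf(
    "SmoothingSpline%s: %d knots on [%g, %g] s, lambda = %g\n",
    if (is.na(object@metaboliteId)) "" else
      sprintf(" '%s'", object@metaboliteId),
    z, object@knots[1], object@knots[z], object@lambda))
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d metabolites, %d reactions\n",
              length(object@metabolites), length(object@reactions)))
  if (length(object@metabolites))
    cat("  metabolites:",
        paste(utils::head(object@metabolites, 8), collapse = ", "),
        if (length(object@metabolites) > 8) "..." else "", "\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf("InteractionMatrix: %d x %d, %d nonzero entries\n",
              nrow(object@entries), ncol(object@entries),
              sum(object@entries)))
})

setMethod("show", "OmegaSeries", function(object) {
  cat(sprintf(
    "OmegaSeries %s -> %s: %d grid points, %d masked (epsilon = %.3g)\n",
    object@source, object@target, length(object@grid),
    sum(object@mask), object@epsilon))
})

setMethod("show", "MassActionModel", function(object) {
  cat(sprintf("MassActionModel: %d metabolites, %d reactions, k in [%g, %g]\n",
              length(object@network@metabolites),
              length(object@network@reactions),
              min(object@rateConstants), max(object@rateConstants)))
})

## ---------------------------------------------------------------- ##
## accessors                                                         ##
## ---------------------------------------------------------------- ##

#' @rdname metaboliteId
#' @export
setMethod("metaboliteId", "ReplicateSeries", function(x) x@metaboliteId)
#' @rdname metaboliteId
#' @export
setMethod("metaboliteId", "SmoothingSpline", function(x) x@metaboliteId)

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "ReplicateSeries", function(x) x@times)
#' @rdname seriesReplicates
#' @export
setMethod("seriesReplicates", "ReplicateSeries", function(x) x@replicates)
#' @rdname seriesMeans
#' @export
setMethod("seriesMeans", "ReplicateSeries",
          function(x) if (length(x@means)) x@means else NULL)
#' @rdname seriesSds
#' @export
setMethod("seriesSds", "ReplicateSeries",
          function(x) if (length(x@sds)) x@sds else NULL)
#' @rdname seriesWeights
#' @export
setMethod("seriesWeights", "ReplicateSeries",
          function(x) if (length(x@weights)) x@weights else NULL)
#' @rdname isSummarized
#' @export
setMethod("isSummarized", "ReplicateSeries",
          function(x) length(x@weights) > 0L)

#' @rdname splineKnots
#' @export
setMethod("splineKnots", "SmoothingSpline", function(x) x@knots)
#' @rdname splineCoefficients
#' @export
setMethod("splineCoefficients", "SmoothingSpline", function(x) x@coefficients)
#' @rdname splineLambda
#' @export
setMethod("splineLambda", "SmoothingSpline", function(x) x@lambda)

#' @rdname metabolites
#' @export
setMethod("metabolites", "ReactionNetwork", function(x) x@metabolites)
#' @rdname metabolites
#' @export
setMethod("metabolites", "InteractionMatrix",
          function(x) rownames(x@entries))
#' @rdname reactions
#' @export
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)
#' @rdname interactionEntries
#' @export
setMethod("interactionEntries", "InteractionMatrix", function(x) x@entries)

#' @rdname omegaGrid
#' @export
setMethod("omegaGrid", "OmegaSeries", function(x) x@grid)
#' @rdname omegaValues
#' @export
setMethod("omegaValues", "OmegaSeries", function(x) x@values)
#' @rdname omegaMask
#' @export
setMethod("omegaMask", "OmegaSeries", function(x) x@mask)

#' @rdname modelNetwork
#' @export
setMethod("modelNetwork", "MassActionModel", function(x) x@network)
#' @rdname rateConstants
#' @export
setMethod("rateConstants", "MassActionModel", function(x) x@rateConstants)
#' @rdname initialConcentrations
#' @export
setMethod("initialConcentrations", "MassActionModel",
          function(x) x@initialConcentrations)
#' @rdname metabolites
#' @export
setMethod("metabolites", "MassActionModel",
          function(x) x@network@metabolites)
#' @rdname reactions
#' @export
setMethod("reactions", "MassActionModel", function(x) x@network@reactions)
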