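#' Metabolite identifier of an object
#'
#' @param x a \linkS4class{ReplicateSeries} or \linkS4class{SmoothingSpline}.
#' @return Character scalar.
#' @export
setGeneric("metaboliteId", function(x) standardGeneric("metaboliteId"))

#' Sampling times of an object (seconds)
#'
#' @param x a \linkS4class{ReplicateSeries}.
#' @return Numeric vector of strictly increasing times in seconds.
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' Replicate concentration values per time point
#'
#' @param x a \linkS4class{ReplicateSeries}.
#' @return List of numeric vectors (mM), one per time point.
#' @export
setGeneric("seriesReplicates", function(x) standardGeneric("seriesReplicates"))

#' Per-time-point mean concentrations (mM)
#' @param x a \linkS4class{ReplicateSeries}.
#' @return Numeric vector, or `NULL` if the series has not been summarized.
#' @export
setGeneric("seriesMeans", function(x) standardGeneric("seriesMeans"))

#' Per-time-point sample standard deviations (mM)
#' @param x a \linkS4class{ReplicateSeries}.
#' @return Numeric vector (`NA` where fewer than 2 replicates), or `NULL`.
#' @export
setGeneric("seriesSds", function(x) standardGeneric("seriesSds"))

#' Per-time-point inverse-variance weights (mM^-2)
#' @param x a \linkS4class{ReplicateSeries}.
#' @return Numeric vector of finite, strictly positive weights, or `NULL`.
#' @export
setGeneric("seriesWeights", function(x) standardGeneric("seriesWeights"))

#' Has a series been summarized?
#' @param x a \linkS4class{ReplicateSeries}.
#' @return Logical scalar.
#' @export
setGeneric("isSummarized", function(x) standardGeneric("isSummarized"))

#' Populate means, standard deviations and inverse-variance weights
#'
#' @param x a \linkS4class{ReplicateSeries} (or list of them).
#' @param ... policy arguments, see methods.
#' @export
setGeneric("summarizeReplicates",
           function(x, ...) standardGeneric("summarizeReplicates"))

#' Knot (node) times of a fitted spline (seconds)
#' @param x a \linkS4class{SmoothingSpline}.
#' @return Numeric vector.
#' @export
setGeneric("splineKnots", function(x) standardGeneric("splineKnots"))

#' Piecewise cubic coefficients of a fitted spline
#' @param x a \linkS4class{SmoothingSpline}.
#' @return `(z-1) x 4` matrix with columns `alpha, beta, gamma, delta`: on
#'   subinterval `[t_j, t_(j+1)]` the piece is
#'   `alpha + beta*u + gamma*u^2 + delta*u^3` with `u = t - t_j`.
#' @export
setGeneric("splineCoefficients",
           function(x) standardGeneric("splineCoefficients"))

#' Smoothing factor used for a fit
#' @param x a \linkS4class{SmoothingSpline}.
#' @return Non-negative numeric scalar.
#' @export
setGeneric("splineLambda", function(x) standardGeneric("splineLambda"))

#' Metabolite identifiers of a network or matrix
#' @param x a \linkS4class{ReactionNetwork} or \linkS4class{InteractionMatrix}.
#' @return Character vector in declared order.
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' Reaction list of a network
#' @param x a \linkS4class{ReactionNetwork}.
#' @return List of reaction records.
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' 0/1 entries of an interaction matrix
#' @param x an \linkS4class{InteractionMatrix}.
#' @return Integer `n x n` matrix with metabolite dimnames; rows index
#'   metabolic functions, columns index the metabolites they depend on.
#' @export
setGeneric("interactionEntries",
           function(x) standardGeneric("interactionEntries"))

#' Evaluation grid of an omega series (seconds)
#' @param x an \linkS4class{OmegaSeries}.
#' @return Numeric vector.
#' @export
setGeneric("omegaGrid", function(x) standardGeneric("omegaGrid"))

#' Omega values (1/s); NA where masked
#' @param x an \linkS4class{OmegaSeries}.
#' @return Numeric vector aligned with [omegaGrid()].
#' @export
setGeneric("omegaValues", function(x) standardGeneric("omegaValues"))

#' Excluded-domain mask of an omega series
#'
#' `TRUE` marks grid points where the denominator metabolic function is at
#' or near zero and the ratio is undefined.
#' @param x an \linkS4class{OmegaSeries}.
#' @return Logical vector aligned with [omegaGrid()].
#' @export
setGeneric("omegaMask", function(x) standardGeneric("omegaMask"))

#' Element-wise absolute value of an omega series
#' @param x an \linkS4class{OmegaSeries}.
#' @return An \linkS4class{OmegaSeries} with `|omega|` values, mask preserved.
#' @export
setGeneric("absOmega", function(x) standardGeneric("absOmega"))

#' Time of the maximum absolute omega value
#'
#' @param x an \linkS4class{OmegaSeries}.
#' @return Time in seconds of the earliest grid point attaining the maximum
#'   `|omega|` among unmasked points.
#' @export
setGeneric("peakTime", function(x) standardGeneric("peakTime"))

#' Reaction network of a model
#' @param x a \linkS4class{MassActionModel}.
#' @return A \linkS4class{ReactionNetwork}.
#' @export
setGeneric("modelNetwork", function(x) standardGeneric("modelNetwork"))

#' Per-reaction rate constants of a model
#' @param x a \linkS4class{MassActionModel}.
#' @return Named non-negative numeric vector.
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))

#' Initial concentrations of a model (mM)
#' @param x a \linkS4class{MassActionModel}.
#' @return Named non-negative numeric vector.
#' @export
setGeneric("initialConcentrations",
           function(x) standardGeneric("initialConcentrations"))
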