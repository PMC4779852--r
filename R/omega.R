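#' @include AllClasses.R
NULL

#' Compute the interaction-ratio series omega(a->b, t)
#'
#' For a source (effector) metabolite a and a target metabolite b,
#' \deqn{\omega(a \to b, t) = \frac{d f_b / dt}{f_a(t)}}
#' where the metabolic function f is the first and `d f/dt` the second
#' time derivative of the fitted smoothing splines. The unit is 1/s.
#' The exact-zero domain exclusion of the continuous definition becomes a
#' relative band in floating point: grid points with
#' `|f_a| <= epsilonRel * max |f_a|` (maximum over the grid) are masked
#' and their values set to `NA`. If every point is masked — e.g. a
#' constant source series — the returned object carries all-`TRUE` mask
#' and a warning is emitted.
#'
#' @param splineA source-metabolite fit (denominator, order-1 derivative).
#' @param splineB target-metabolite fit (numerator, order-2 derivative).
#' @param grid evaluation times (s); default `gridSize` uniform points over
#'   the common fitted interval of both splines.
#' @param epsilonRel relative masking threshold in (0, 1); default 1e-3.
#' @param gridSize grid length when `grid` is not supplied.
#' @return An \linkS4class{OmegaSeries}.
#' @examples
#' t <- seq(0, 200, length.out = 30)
#' spA <- fitSmoothingSpline(t, exp(-0.01 * t), lambda = 0)
#' om <- omegaSeries(spA, spA)   # self-pair of a first-order decay
#' stats::median(omegaValues(om), na.rm = TRUE)  # ~ -k = -0.01
#' @seealso [absOmega()], [peakTime()], [classifyStrength()],
#'   [omegaAllPairs()]
#' @export
omegaSeries <- function(splineA, splineB, grid = NULL, epsilonRel = 1e-3,
                        gridSize = 200L) {
  stopifnot(is(splineA, "SmoothingSpline"), is(splineB, "SmoothingSpline"))
  if (epsilonRel <= 0 || epsilonRel >= 1)
    stop("'epsilonRel' must lie strictly between 0 and 1")
  ka <- splineA@knots; kb <- splineB@knots
  lo <- max(ka[1], kb[1]); hi <- min(ka[length(ka)], kb[length(kb)])
  if (lo >= hi)
    stop("the fitted intervals of the two splines do not overlap")
  if (is.null(grid)) grid <- seq(lo, hi, length.out = gridSize)
  tol <- 1e-9 * (hi - lo)
  if (any(grid < lo - tol) || any(grid > hi + tol))
    stop(sprintf("grid extends outside the common fitted interval [%g, %g]",
                 lo, hi))
  fa  <- evaluateSpline(splineA, grid, order = 1L)
  dfb <- evaluateSpline(splineB, grid, order = 2L)
  eps <- epsilonRel * max(abs(fa))
  mask <- abs(fa) <= eps
  vals <- rep(NA_real_, length(grid))
  vals[!mask] <- dfb[!mask] / fa[!mask]
  if (all(mask))
    warning(sprintf(
      "omega(%s -> %s): denominator metabolic function is zero %s",
      splineA@metaboliteId, splineB@metaboliteId,
      "(or near zero) everywhere; all grid points masked"))
  new("OmegaSeries",
      source = splineA@metaboliteId, target = splineB@metaboliteId,
      grid = as.numeric(grid), values = vals, mask = mask, epsilon = eps)
}

#' @rdname absOmega
#' @export
setMethod("absOmega", "OmegaSeries", function(x)
  initialize(x, values = abs(x@values)))

#' Classify per-time-point interaction strength
#'
#' Labels each unmasked grid point by the magnitude of omega: `|omega| >=
#' high` is `"strong"` (the effector dominates the target's function
#' dynamics), `|omega| <= low` is `"weak"`, anything between is
#' `"intermediate"`. Masked points get `NA`.
#'
#' @param series an \linkS4class{OmegaSeries}.
#' @param low,high thresholds in 1/s with `0 < low < high`.
#' @return Character vector aligned with the grid.
#' @export
classifyStrength <- function(series, low, high) {
  stopifnot(is(series, "OmegaSeries"))
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && low < high))
    stop("thresholds must satisfy 0 < low < high")
  a <- abs(series@values)
  out <- rep(NA_character_, length(a))
  ok <- !series@mask
  out[ok] <- ifelse(a[ok] >= high, "strong",
                    ifelse(a[ok] <= low, "weak", "intermediate"))
  out
}

#' @rdname peakTime
#' @details The peak is the earliest grid time attaining the maximum
#'   `|omega|` among unmasked points (ties break to the earlier time).
#' @export
setMethod("peakTime", "OmegaSeries", function(x) {
  ok <- which(!x@mask)
  if (!length(ok))
    stop(sprintf("omega(%s -> %s): all grid points are masked, no peak",
                 x@source, x@target))
  a <- abs(x@values[ok])
  x@grid[ok[which.max(a)]]   # which.max returns the first maximum
})

#' Omega series for every interacting pair of an interaction matrix
#'
#' For each entry Y(i, j) = 1 computes the series with source = column
#' metabolite j (the effector, denominator) and target = row metabolite i
#' (the function whose dynamics are read, numerator). Entries of 0 are
#' never computed.
#'
#' @param fits named list of \linkS4class{SmoothingSpline}, one per
#'   metabolite id used in `Y`.
#' @param Y an \linkS4class{InteractionMatrix}.
#' @inheritParams omegaSeries
#' @return Named list of \linkS4class{OmegaSeries} (names
#'   `"source->target"`), one per 1-entry of `Y`, in row-major order.
#' @export
omegaAllPairs <- function(fits, Y, grid = NULL, epsilonRel = 1e-3,
                          gridSize = 200L) {
  stopifnot(is(Y, "InteractionMatrix"))
  e <- Y@entries
  required <- rownames(e)[rowSums(e) > 0 | colSums(e) > 0]
  missing <- setdiff(required, names(fits))
  if (length(missing))
    stop("no fitted spline for metabolite(s): ",
         paste(missing, collapse = ", "))
  out <- list()
  for (i in rownames(e)) for (j in colnames(e)) {
    if (e[i, j] != 1L) next
    out[[sprintf("%s->%s", j, i)]] <-
      omegaSeries(fits[[j]], fits[[i]], grid = grid,
                  epsilonRel = epsilonRel, gridSize = gridSize)
  }
  out
}

#' Export omega series as long-format and summary tables
#'
#' The long table has columns `source`, `target`, `t_s`, `omega_per_s`,
#' `abs_omega_per_s`, `masked`, `label`; the summary table one row per
#' pair with `source`, `target`, `peak_time_s`, `peak_abs_omega_per_s`
#' (`NA` for all-masked pairs).
#'
#' @param series list of \linkS4class{OmegaSeries} (as from
#'   [omegaAllPairs()]).
#' @param path output path of the long table.
#' @param summaryPath optional output path of the per-pair summary.
#' @param low,high strength thresholds (1/s) for the `label` column.
#' @return List with the two data.frames, invisibly.
#' @export
writeOmegaTables <- function(series, path, summaryPath = NULL,
                             low = 1e-4, high = 1e-2) {
  if (is(series, "OmegaSeries")) series <- list(series)
  long <- do.call(rbind, lapply(series, function(s)
    data.frame(source = s@source, target = s@target, t_s = s@grid,
               omega_per_s = s@values, abs_omega_per_s = abs(s@values),
               masked = s@mask,
               label = classifyStrength(s, low, high))))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- do.call(rbind, lapply(series, function(s) {
    allMasked <- all(s@mask)
    data.frame(source = s@source, target = s@target,
               peak_time_s = if (allMasked) NA_real_ else peakTime(s),
               peak_abs_omega_per_s = if (allMasked) NA_real_ else
                 max(abs(s@values[!s@mask])))
  }))
  if (!is.null(summaryPath))
    utils::write.table(summary, summaryPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(long = long, summary = summary))
}
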