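#' @include AllClasses.R
NULL

## Band matrices of the natural-spline curvature form.
## For knots t_1 < ... < t_z with h_j = t_{j+1} - t_j:
##   Q is z x (z-2), R is (z-2) x (z-2) tridiagonal, such that the interior
##   second derivatives gam of the natural interpolating spline through g
##   satisfy R gam = Q' g, and the curvature penalty is
##   Int S''(t)^2 dt = gam' R gam  (exact, since S'' is piecewise linear).
.bandMatrices <- function(times) {
  z <- length(times)
  h <- diff(times)
  Q <- matrix(0, z, z - 2L)
  R <- matrix(0, z - 2L, z - 2L)
  for (j in seq_len(z - 2L)) {          # interior knot index j+1
    Q[j,     j] <- 1 / h[j]
    Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
    Q[j + 2, j] <- 1 / h[j + 1]
    R[j, j] <- (h[j] + h[j + 1]) / 3
    if (j < z - 2L) R[j, j + 1] <- R[j + 1, j] <- h[j + 1] / 6
  }
  list(Q = Q, R = R, h = h)
}

## Piecewise cubic coefficients from node values g and full second
## derivative vector gam (gam[1] = gam[z] = 0 for a natural spline).
.coefFromNodes <- function(times, g, gam) {
  z <- length(times)
  h <- diff(times)
  j <- seq_len(z - 1L)
  alpha <- g[j]
  gammaC <- gam[j] / 2
  delta <- (gam[j + 1L] - gam[j]) / (6 * h)
  beta  <- (g[j + 1L] - g[j]) / h - h * (2 * gam[j] + gam[j + 1L]) / 6
  m <- cbind(alpha = alpha, beta = beta, gamma = gammaC, delta = delta)
  rownames(m) <- NULL
  m
}

#' Fit an inverse variance-weighted cubic smoothing spline
#'
#' Minimises
#' \deqn{\sum_{j=1}^{z} w_j\,[y_j - S(t_j)]^2 +
#'       \lambda \int_{t_1}^{t_z} S''(t)^2\,dt}
#' over natural cubic splines S with knots at the data times. With
#' `lambda = 0` the fit interpolates the node values exactly; as
#' `lambda` grows the fit approaches the weighted least-squares straight
#' line. The minimiser is computed from the banded normal equations
#' `(R + lambda Q' W^-1 Q) gam = Q' y` for the interior second
#' derivatives, then `g = y - lambda W^-1 Q gam` — numerically stable for
#' any `lambda >= 0` including very large values.
#'
#' `lambda` multiplies the curvature penalty directly; see
#' [lambdaToSmoothParam()] for the conversion to the convex-combination
#' convention `p = 1/(1 + lambda)` used by some library routines.
#'
#' @param times strictly increasing numeric vector of z >= 2 node times
#'   (s).
#' @param values node values (mM), typically per-time-point means.
#' @param weights finite, strictly positive weights (mM^-2), typically
#'   inverse replicate variances; unit weights by default.
#' @param lambda non-negative smoothing factor.
#' @param metaboliteId optional id stored with the fit.
#' @return A \linkS4class{SmoothingSpline}.
#' @examples
#' sp <- fitSmoothingSpline(c(0, 10, 20, 30), c(1, 3, 2, 5), lambda = 0)
#' evaluateSpline(sp, c(0, 10, 20, 30))      # reproduces the node values
#' @seealso [evaluateSpline()], [splineObjective()], [selectLambdaGCV()]
#' @export
fitSmoothingSpline <- function(times, values, weights = NULL, lambda = 0,
                               metaboliteId = NA_character_) {
  times <- as.numeric(times); values <- as.numeric(values)
  z <- length(times)
  if (z < 2L) stop("at least 2 nodes are required")
  if (anyNA(times) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (length(values) != z) stop("'values' must match 'times' in length")
  if (is.null(weights)) weights <- rep(1, z)
  if (length(weights) != z || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop("'weights' must be finite, strictly positive and of length z")
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")

  if (z == 2L) {
    message("z = 2 nodes: the fit is the interpolating line for any lambda")
    g <- values
    gam <- c(0, 0)
  } else {
    bm <- .bandMatrices(times)
    B <- crossprod(bm$Q, bm$Q / weights)       # Q' W^-1 Q
    gamInt <- solve(bm$R + lambda * B, crossprod(bm$Q, values))
    g <- values - lambda * (bm$Q %*% gamInt) / weights
    gam <- c(0, drop(gamInt), 0)
    g <- drop(g)
  }
  new("SmoothingSpline", metaboliteId = as.character(metaboliteId),
      knots = times, coefficients = .coefFromNodes(times, g, gam),
      lambda = lambda)
}

#' Evaluate a smoothing spline or its derivatives
#'
#' Order 0 returns the smoothed concentration S(t) (mM); order 1 its first
#' time derivative, the metabolic function f(t) = dS/dt (mM/s); order 2 the
#' function dynamics d2S/dt2 (mM/s^2). Derivatives are computed
#' analytically from the stored cubic coefficients, never by numerical
#' differencing. Grid points outside the fitted interval are rejected
#' unless `extrapolate = TRUE`, in which case the boundary cubic pieces are
#' extended.
#'
#' @param spline a \linkS4class{SmoothingSpline}.
#' @param grid numeric vector of evaluation times (s).
#' @param order derivative order, 0, 1 or 2.
#' @param extrapolate allow evaluation outside `[t_1, t_z]`.
#' @return Numeric vector (mM, mM/s or mM/s^2).
#' @export
evaluateSpline <- function(spline, grid, order = 0L, extrapolate = FALSE) {
  stopifnot(is(spline, "SmoothingSpline"))
  order <- as.integer(order)
  if (!order %in% 0:2) stop("'order' must be 0, 1 or 2")
  kn <- spline@knots
  z <- length(kn)
  tol <- 1e-9 * (kn[z] - kn[1])
  if (!extrapolate && (any(grid < kn[1] - tol) || any(grid > kn[z] + tol)))
    stop(sprintf(
      "grid extends outside the fitted interval [%g, %g] s %s",
      kn[1], kn[z], "(set extrapolate = TRUE to force)"))
  j <- findInterval(grid, kn, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), z - 1L)
  u <- grid - kn[j]
  cf <- spline@coefficients
  a <- cf[j, 1]; b <- cf[j, 2]; cc <- cf[j, 3]; d <- cf[j, 4]
  unname(switch(order + 1L,
                a + u * (b + u * (cc + u * d)),
                b + u * (2 * cc + u * 3 * d),
                2 * cc + 6 * d * u))
}

## Second derivatives at the knots, recovered from the stored pieces.
.knotSecondDerivs <- function(spline) {
  cf <- spline@coefficients
  h <- diff(spline@knots)
  zm1 <- nrow(cf)
  c(2 * cf[, 3], 2 * cf[zm1, 3] + 6 * cf[zm1, 4] * h[zm1])
}

#' Penalised objective value of a fitted spline
#'
#' Returns the weighted residual sum of squares at the nodes plus
#' `lambda` times the exact curvature integral
#' `Int S''(t)^2 dt`, computed in closed form from the piecewise-cubic
#' representation (S'' is piecewise linear, so the integral is exact).
#'
#' @param spline a \linkS4class{SmoothingSpline} fitted on `times`.
#' @param times,values,weights the node data the spline was fitted to.
#' @param lambda smoothing factor; defaults to the one stored in the fit.
#' @return List with components `objective`, `rss` (weighted residual sum)
#'   and `penalty` (the curvature integral, without the lambda factor).
#' @export
splineObjective <- function(spline, times, values, weights = NULL,
                            lambda = splineLambda(spline)) {
  stopifnot(is(spline, "SmoothingSpline"))
  if (length(times) != length(spline@knots) ||
      max(abs(times - spline@knots)) >
        1e-9 * max(1, abs(spline@knots)))
    stop("'times' do not match the spline's knots")
  if (is.null(weights)) weights <- rep(1, length(times))
  res <- values - evaluateSpline(spline, times)
  rss <- sum(weights * res^2)
  gam <- .knotSecondDerivs(spline)
  h <- diff(spline@knots)
  j <- seq_along(h)
  pen <- sum(h / 3 * (gam[j]^2 + gam[j] * gam[j + 1L] + gam[j + 1L]^2))
  list(objective = rss + lambda * pen, rss = rss, penalty = pen)
}

#' Select the smoothing factor by generalized cross-validation
#'
#' Minimises the weighted GCV score
#' `(RSS_w / z) / (1 - tr(A)/z)^2`, where `A(lambda)` is the smoother
#' matrix mapping node values to fitted values, over a wide
#' scale-aware grid of `lambda` followed by local refinement. This is the
#' automated alternative to supplying `lambda` explicitly; for
#' reproducibility the chosen value is returned and should be recorded.
#'
#' @inheritParams fitSmoothingSpline
#' @param lambdaRange optional length-2 vector of positive bounds for the
#'   search; defaults to `median(weights) * span^3` times `[1e-10, 1e6]`.
#' @return The selected `lambda` (numeric scalar) with attribute `"gcv"`
#'   giving its GCV score.
#' @export
selectLambdaGCV <- function(times, values, weights = NULL,
                            lambdaRange = NULL) {
  z <- length(times)
  if (z < 4L) stop("GCV selection needs at least 4 nodes")
  if (is.null(weights)) weights <- rep(1, z)
  bm <- .bandMatrices(times)
  B <- crossprod(bm$Q, bm$Q / weights)
  Qty <- crossprod(bm$Q, values)
  gcvOf <- function(loglam) {
    lam <- exp(loglam)
    M <- bm$R + lam * B
    gamInt <- solve(M, Qty)
    resid <- lam * (bm$Q %*% gamInt) / weights   # y - g
    rss <- sum(weights * resid^2)
    edf <- z - lam * sum(diag(solve(M, B)))      # tr(A)
    (rss / z) / (1 - edf / z)^2
  }
  if (is.null(lambdaRange)) {
    ref <- stats::median(weights) * (times[z] - times[1])^3
    lambdaRange <- ref * c(1e-10, 1e6)
  }
  lr <- log(lambdaRange)
  coarse <- seq(lr[1], lr[2], length.out = 61L)
  sc <- vapply(coarse, gcvOf, numeric(1))
  i <- which.min(sc)
  lo <- coarse[max(1L, i - 1L)]; hi <- coarse[min(length(coarse), i + 1L)]
  opt <- stats::optimize(gcvOf, c(lo, hi), tol = 1e-6)
  structure(exp(opt$minimum), gcv = opt$objective)
}

#' Convert between the penalty-factor and convex-combination conventions
#'
#' The objective here uses `lambda` as a direct multiplier of the
#' curvature penalty. Some spline routines instead weight the two terms as
#' `p * RSS + (1 - p) * penalty`; the equivalent parameter is
#' `p = 1/(1 + lambda)`.
#'
#' @param lambda non-negative penalty factor.
#' @param p smoothing parameter in (0, 1].
#' @return The corresponding parameter in the other convention.
#' @export
lambdaToSmoothParam <- function(lambda) 1 / (1 + lambda)

#' @rdname lambdaToSmoothParam
#' @export
smoothParamToLambda <- function(p) (1 - p) / p

#' Export a fitted spline on a dense grid
#'
#' Writes a TSV with columns `t_s`, `S`, `dS_dt`, `d2S_dt2` evaluated on a
#' uniform grid spanning the fitted interval.
#'
#' @param spline a \linkS4class{SmoothingSpline}.
#' @param path output path.
#' @param gridSize number of grid points (default 200).
#' @return The exported data.frame, invisibly.
#' @export
writeFitTable <- function(spline, path, gridSize = 200L) {
  kn <- splineKnots(spline)
  grid <- seq(kn[1], kn[length(kn)], length.out = gridSize)
  df <- data.frame(t_s = grid,
                   S = evaluateSpline(spline, grid, 0L),
                   dS_dt = evaluateSpline(spline, grid, 1L),
                   d2S_dt2 = evaluateSpline(spline, grid, 2L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
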