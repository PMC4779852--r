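# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (band matrices, closed-form penalty) so they can
# serve as cross-checks.

# Composite Simpson quadrature of fun over [a, b] on nPanels panels.
simpson <- function(fun, a, b, nPanels = 1e4) {
  x <- seq(a, b, length.out = nPanels + 1L)
  y <- fun(x)
  h <- (b - a) / nPanels
  h / 6 * sum(y[-length(y)] + 4 * fun(x[-length(x)] + h / 2) + y[-1])
}

# Composite Simpson with the panel budget spread over the knot
# subintervals, so panel edges align with the integrand's derivative
# kinks at the knots.
simpsonOverKnots <- function(fun, knots, nPanels = 1e4) {
  per <- max(2L, ceiling(nPanels / (length(knots) - 1L)))
  sum(vapply(seq_len(length(knots) - 1L), function(j)
    simpson(fun, knots[j], knots[j + 1L], per), numeric(1)))
}

# Curvature penalty of the natural interpolating spline through node
# values g, via quadrature of an independent spline representation
# (stats::splinefun), not the package's closed form.
oraclePenalty <- function(g, times) {
  f <- stats::splinefun(times, g, method = "natural")
  simpsonOverKnots(function(x) f(x, deriv = 2)^2, times, 200L)
}

# Brute-force minimisation of the penalised objective over node values,
# i.e. over the full natural-spline family with knots at the data times:
# the penalty is quadratic in g, so its matrix is recovered by probing
# oraclePenalty with basis vectors and the minimiser follows by direct
# linear algebra.
oracleSplineObjective <- function(times, values, weights, lambda) {
  z <- length(times)
  ei <- function(i) replace(numeric(z), i, 1)
  K <- matrix(0, z, z)
  for (i in seq_len(z)) K[i, i] <- oraclePenalty(ei(i), times)
  for (i in seq_len(z - 1L)) for (j in seq(i + 1L, z)) {
    K[i, j] <- K[j, i] <-
      (oraclePenalty(ei(i) + ei(j), times) - K[i, i] - K[j, j]) / 2
  }
  g <- solve(diag(weights) + lambda * K, weights * values)
  sum(weights * (values - g)^2) + lambda * drop(t(g) %*% K %*% g)
}

# Brute-force interaction matrix: double loop over reactions and their
# substrate/effector lists, per the definition.
oracleInteractionMatrix <- function(network,
                                    reversiblePolicy = "both_directions") {
  mets <- metabolites(network)
  Y <- matrix(0L, length(mets), length(mets),
              dimnames = list(mets, mets))
  for (rx in reactions(network)) {
    net <- sapply(mets, function(m) {
      sum(rx$products$coef[rx$products$id == m]) -
        sum(rx$substrates$coef[rx$substrates$id == m])
    })
    drivers <- c(rx$substrates$id, rx$effectors$id)
    if (rx$reversible && reversiblePolicy == "both_directions")
      drivers <- c(drivers, rx$products$id)
    for (i in mets) for (j in mets)
      if (net[[i]] != 0 && j %in% drivers) Y[i, j] <- 1L
  }
  Y
}

# Per-reaction tally of the stoichiometric matrix.
oracleStoichiometry <- function(network) {
  mets <- metabolites(network)
  rxns <- reactions(network)
  N <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, vapply(rxns, `[[`, character(1),
                                           "name")))
  for (r in seq_along(rxns)) for (m in mets) {
    rx <- rxns[[r]]
    N[m, r] <- sum(rx$products$coef[rx$products$id == m]) -
      sum(rx$substrates$coef[rx$substrates$id == m])
  }
  N
}

# Random small network, emitted through the public text syntax so the
# parser is exercised too. Returns the text lines.
randomNetworkText <- function(nMet = 5L, nRxn = 5L) {
  mets <- paste0("M", seq_len(nMet))
  lines <- vapply(seq_len(nRxn), function(r) {
    ns <- sample(1:2, 1); np <- sample(0:2, 1)
    subs <- sample(mets, ns)
    prods <- if (np > 0) sample(setdiff(mets, subs), min(np, nMet - ns))
             else character(0)
    term <- function(ids) paste(
      ifelse(stats::runif(length(ids)) < 0.3,
             paste(sample(2:3, length(ids), TRUE), ids), ids),
      collapse = " + ")
    arrow <- if (stats::runif(1) < 0.3) "<->" else "->"
    line <- paste(term(subs), arrow,
                  if (length(prods)) term(prods) else "")
    if (stats::runif(1) < 0.25) {
      eff <- sample(mets, 1)
      line <- paste0(line, " | ",
                     sample(c("inhibitor", "activator"), 1), ": ", eff)
    }
    line
  }, character(1))
  lines
}

# Noise-free first-order decay fixture: lambda = 0 spline through exact
# exponential samples.
decaySpline <- function(k = 0.01, z = 30L, nHalfLives = 3) {
  t <- seq(0, nHalfLives * log(2) / k, length.out = z)
  fitSmoothingSpline(t, exp(-k * t), lambda = 0, metaboliteId = "A")
}
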