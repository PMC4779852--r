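---
title: "Methods: weighted smoothing splines and the omega interaction statistic"
author: "omegaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted smoothing splines and the omega interaction statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegaflux)
```

## The model

A metabolic network of n metabolites and k reactions obeys the balance
equations

$$\frac{d}{dt}\,M(t) = N\,v(M, p, t) = f(M, p, t),$$

where $N$ is the $n \times k$ stoichiometric matrix, $v$ the vector of
reaction rates and $p$ the (generally unknown) kinetic parameters. The
component $f_i$, the **metabolic function** of metabolite $i$, is the net
rate of change of its pool. The central observation exploited here is
that $f_i$ — and its own time derivative $df_i/dt$, the function's
**dynamics** — can be estimated directly from replicated concentration
measurements as the first and second derivatives of a smoothed time
course, with no kinetic model.

Two estimated derivative series are then related through the
**interaction-ratio statistic**

$$\omega(a \to b, t) = \frac{d f_b/dt}{f_a(t)},
  \qquad t \notin D = \{\,t : f_a(t) = 0\,\},$$

whose unit is $\mathrm{mM\,s^{-2}} / \mathrm{mM\,s^{-1}} = \mathrm{s^{-1}}$,
a frequency: how fast the target's metabolic function turns over, per
unit of the effector's net rate. Which pairs $(a, b)$ are meaningful is
decided by the network alone: the binary **interaction matrix** $Y$ has
$Y_{ij} = 1$ exactly when metabolite $j$ is a substrate or annotated
effector (inhibitor, activator, SBML modifier) of at least one reaction
with nonzero net stoichiometry for metabolite $i$ — the sparsity pattern
of the system's Jacobian. For the textbook first-order decay
$A \xrightarrow{k} B$, $A(t) = A_0 e^{-kt}$ gives
$\omega(A \to A, t) = -k$ at every $t$, the corresponding Jacobian entry;
this is the package's analytic validation case.

Interpretation of $|\omega|$ follows its limits: $|\omega| \to \infty$
near a time $\tau$ marks a strong influence of the effector on the
target's function (the dynamics outweigh the effector's rate), while
$|\omega| \to 0$ marks a weak one. `classifyStrength()` turns this into
per-time-point labels with user thresholds.

## Estimating derivatives: the weighted smoothing spline

Given means $\bar y_j$ at times $t_1 < \dots < t_z$ with weights $w_j$,
`fitSmoothingSpline()` minimises

$$\sum_{j=1}^{z} w_j\,[\bar y_j - S(t_j)]^2
  + \lambda \int_{t_1}^{t_z} S''(t)^2\,dt$$

over natural cubic splines with knots at the data times — the classical
variational family for this objective (any smoother curve could lower
neither term). The solver uses the banded normal equations for the
interior second derivatives ($(R + \lambda Q^\top W^{-1} Q)\gamma =
Q^\top y$, then $g = y - \lambda W^{-1} Q \gamma$), which is numerically
stable from $\lambda = 0$ (exact interpolation) through
$\lambda = 10^{12}$ (indistinguishable from the weighted least-squares
line). Derivatives are read analytically from the stored cubic pieces;
no numerical differencing is ever involved.

Choices made where the method leaves room:

* **Weights.** $w_j = \sigma_j^{-2}$, the inverse sample variance of the
  replicates (denominator $r_j - 1$). Where that is undefined — a single
  replicate, or identical replicates — the weight is capped at
  $\kappa \cdot \max(\text{finite weights of the series})$ with
  $\kappa = 10$ by default, keeping the objective finite while still
  pinning low-noise points tightly; a series with no finite weight at
  all falls back to unit weights. Both cases warn and are logged by the
  pipeline. Missing replicate values are dropped (reducing $r_j$); a
  time point losing all replicates is removed with a warning. No outlier
  handling or imputation beyond this.
* **$\lambda$ convention.** $\lambda$ multiplies the penalty directly,
  so its scale depends on the time units and weights
  ($\lambda \sim \bar w \cdot \text{span}^3$ balances the two terms).
  `lambdaToSmoothParam()` documents the conversion $p = 1/(1+\lambda)$
  to the convex-combination convention of some library routines;
  `stats::smooth.spline`'s internally rescaled parameter maps as
  $\lambda = \lambda_{ss} \cdot \text{span}^3 \cdot \bar w$, which the
  test suite uses as an independent cross-check of the fit.
* **$\lambda$ selection.** The primary mode is a user-supplied $\lambda$
  (global or per metabolite): reproducibility first. Generalized
  cross-validation (`selectLambdaGCV()`, minimising
  $(RSS_w/z)/(1 - \mathrm{tr}\,A/z)^2$ over a coarse-then-refined grid
  on $\log\lambda$) is the clearly-labelled automated alternative. Be
  aware that at small $z$ (around 12) the GCV curve is often bimodal;
  two correct implementations can land in different minima. The chosen
  value is always recorded in the run log.
* **Boundaries.** Natural conditions ($S'' = 0$ at $t_1, t_z$).
  Derivative estimates adjacent to the boundaries are therefore biased
  wherever the true curvature does not vanish there, which is why
  validation statistics below are taken over the interior of the fitted
  interval. Extrapolation outside $[t_1, t_z]$ is refused unless
  explicitly enabled. Periodic (cycle-closing) boundary conditions are
  not implemented, even though diurnal applications are cyclic.
* **Degenerate inputs.** $z = 2$ returns the interpolating line for any
  $\lambda$ (with a note); exactly collinear data yield identically zero
  curvature at any $\lambda$. Interpolation assertions use a tolerance
  of $10^{-9}$ relative to the value scale.
* **No shape constraints.** Smoothed concentrations may dip negative;
  monotonicity or positivity constraints are out of scope.

Time is seconds internally (readers convert from declared `s`, `min`,
`h`, `d`), which fixes ω's unit to s⁻¹; refitting on times expressed in
hours scales ω by exactly 3600, a unit contract the tests assert.

## Masking the excluded domain

The continuous definition excludes single points where $f_a = 0$; in
floating point a band is required. A grid point is masked when
$|f_a| \le \varepsilon_{rel} \cdot \max_{\text{grid}} |f_a|$, default
$\varepsilon_{rel} = 10^{-3}$: near-zero denominators make ω numerically
meaningless in exactly the way the $|\omega| \to \infty$ limit reads
biologically. Masked values are `NA`, the mask and the absolute
threshold actually applied travel with the `OmegaSeries`, and a series
masked everywhere (e.g. a constant effector) warns rather than errors.
The evaluation grid defaults to 200 uniform points over the common
fitted interval; |ω| peaks (`peakTime()`) resolve ties to the earliest
grid time, keeping outputs deterministic.

ω is computed from spline fits of the per-time-point *means* (the
weights already carry the replicate information); per-replicate ω
ensembles and confidence bands on ω are not provided.

## The synthetic-data generator

`simulateTrajectories()` integrates mass-action kinetics
($v_r = k_r \prod c_s^{\text{multiplicity}}$) with `deSolve::lsoda` at
rtol $10^{-8}$ / atol $10^{-10}$; only irreversible reactions are
simulated (write a reversible step as its two directions).
`makeReplicates()` adds independent multiplicative Gaussian noise —
constant coefficient of variation, the simplest model under which
inverse-variance weighting is informative — with an absolute floor
$\sigma_{min} = 10^{-6}$ mM preventing zero-variance artifacts at true
zeros, truncation of negative draws at 0, and full seed determinism
(the caller's RNG state is untouched).

Three benchmark scenarios define the package's study conditions:

* `decay`: $A \xrightarrow{0.01/\mathrm{s}} B$, $A_0 = 1$ mM, 12 time
  points over three half-lives, 5 replicates, 5% CV — the analytic
  ω = −k case, noise-free and noisy.
* `chain4`: the worked four-metabolite chain A→B→C→D used for the
  interaction-matrix example.
* `two_phase`: two independent two-step chains, A→B→C at
  (0.01, 0.005) s⁻¹ and D→E→F at (0.0025, 0.00125) s⁻¹, sampled at 24
  points over 0–700 s. Each intermediate's net rate changes sign when
  its pool turns over (139 s for B, 555 s for E); |ω| of the self-pairs
  spikes at the edge of the masked band around that sign change, so the
  fast chain's peak precedes the slow chain's by construction. The rates
  and window were chosen so each denominator stays above 1% of its
  maximum away from its single sign change — otherwise replicate noise
  can manufacture spurious near-zero denominators and scatter the peak.
  The scenario emulates, qualitatively, an early primary-metabolism
  response followed by a delayed secondary-metabolism one.

What the generator does **not** emulate: correlated replicate errors,
heteroscedasticity beyond constant CV, missingness patterns, sampling
jitter, Michaelis–Menten or allosteric kinetics, and diurnal
periodicity. Passing tests on these scenarios therefore demonstrate
correctness of the estimators under clean, known kinetics — not
robustness to every pathology of real metabolomic data.

## Problem sizes and numerical checks

The test suite works at small scale by design: spline oracle instances
use $z \le 10$ nodes (the penalised objective is verified against a
brute-force minimisation whose penalty matrix is probed, basis vector by
basis vector, from an independent spline representation with
knot-aligned Simpson quadrature — exact for the piecewise-quadratic
integrand); interaction matrices are checked against a brute-force
definition scan on 20 random networks of up to 6 metabolites; derivative
evaluation against central finite differences at $10^{-5}$ relative;
the noisy ω-recovery condition runs one seeded realisation of the
`decay` scenario and requires the median interior (central 60%) ω to be
within 15% of −k. All randomised tests fix their seeds; the pipeline
itself is deterministic, and rerunning a configuration reproduces every
output byte for byte.

## Known limitations

* ω approaches Jacobian entries only in the infinitesimal limit; on
  finite sampling intervals it is a time-windowed analogue, and no
  claim is made (or tested) that $|\omega|$ converges to $|J|$ entries
  on real data.
* The interaction matrix is built from explicit network annotation
  only; allosteric links are included solely when declared as
  effectors. Genome-scale reconstructions (compartments, GPR rules,
  exchange fluxes) are out of scope.
* GCV instability at small $z$ (above) means automated smoothing can
  occasionally under-smooth; for publication analyses a recorded,
  user-chosen $\lambda$ is preferable.
* No confidence bands on ω and no causal analysis; the statistic flags
  *when* a dependency is perturbed, not directionality or mechanism.
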