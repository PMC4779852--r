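# omegaflux

Functional interpretation of metabolomic time series: weighted smoothing
splines, metabolic functions, and the interaction-ratio statistic
ω(a→b, t).

## The problem

Replicated metabolite concentration time courses (diurnal profiles,
stress-response series, ...) carry more information than the
concentrations themselves: the *rates* at which pools change, and how
those rates respond to the concentrations of biochemically connected
metabolites, reflect the regulatory state of the underlying network. For
a network with stoichiometric matrix **N** and rate vector **v**, each
metabolite balance follows

    dM_i/dt = [N v(M, p, t)]_i = f_i(M, p, t)

and `f_i` — the *metabolic function* of metabolite i — is estimable from
data as the first time derivative of a smoothed concentration time
course, without knowing the kinetic parameters `p`.

`omegaflux` implements this strategy end to end for experimentalists and
modellers working with replicated metabolomic time series:

1. **Per-time-point statistics.** Replicate concentrations `c_ij,k` (mM)
   yield means, sample standard deviations and inverse-variance weights
   `w_ij = σ_ij⁻²`, so precisely measured time points pin the fit more
   tightly.
2. **Weighted smoothing spline.** A natural cubic spline `S(t)` with
   knots at the data times minimises

       Σ_j w_j [ȳ_j − S(t_j)]² + λ ∫ S″(t)² dt ,   λ ≥ 0.

   λ = 0 interpolates the means; growing λ approaches the weighted
   least-squares line. `S′` is the metabolic function `f_i` (mM/s), `S″`
   its dynamics (mM/s²), both evaluated analytically from the cubic
   pieces.
3. **Interaction matrix.** From a reaction list (or SBML file) a binary
   n×n matrix **Y** is built: entry (i, j) = 1 iff metabolite j is a
   substrate or annotated effector (inhibitor/activator) of a reaction
   that changes metabolite i — the sparsity pattern a Jacobian would
   have.
4. **The ω statistic.** For each pair with Y = 1,

       ω(a→b, t) = (d f_b / dt) / f_a(t)     [unit: 1/s]

   relates the dynamics of target b's metabolic function to the net rate
   of effector a. Time points where `f_a ≈ 0` (the statistic's excluded
   domain) are masked. Large |ω| flags time points at which the
   biochemical dependency of b on a is strongly perturbed; for a pure
   first-order decay A →(k) B the self-pair recovers the Jacobian entry,
   ω(A→A, t) = −k.

A mass-action ODE simulator with replicate noise (`benchmarkScenario()`,
`simulateTrajectories()`, `makeReplicates()`) generates benchmark data
with known ground truth, standing in for experimental datasets.

## Worked example

Recover the rate constant of a first-order decay from noisy replicates:

```r
library(omegaflux)

sc     <- benchmarkScenario("decay")            # A -> B, k = 0.01/s
traj   <- simulateTrajectories(sc$model, sc$times)
series <- makeReplicates(traj, sc$times, cv = 0.05, r = 5, seed = 1,
                         summarize = TRUE)

A      <- series$A
lambda <- selectLambdaGCV(seriesTimes(A), seriesMeans(A), seriesWeights(A))
fitA   <- fitSmoothingSpline(seriesTimes(A), seriesMeans(A),
                             seriesWeights(A), lambda, metaboliteId = "A")
fitA
#> SmoothingSpline 'A': 12 knots on [0, 207.944] s, lambda = 58628

om <- omegaSeries(fitA, fitA)
om
#> OmegaSeries A -> A: 200 grid points, 0 masked (epsilon = 9.38e-06)
median(omegaValues(om), na.rm = TRUE)
#> [1] -0.009339676
```

The median ω(A→A, t) of −0.0093 s⁻¹ recovers the true Jacobian entry
−k = −0.01 s⁻¹ to within 7% from 5 replicates with 5% noise at 12 time
points. The interaction matrix of the worked four-metabolite chain:

```r
interactionEntries(interactionMatrix(parseReactions(
  "A -> B\nB -> C\nC -> D")))
#>   A B C D
#> A 1 0 0 0
#> B 1 1 0 0
#> C 0 1 1 0
#> D 0 0 1 0
```

Row B, column A reads: the metabolic function of B depends on the
concentration of A. The same analysis runs from the shell:

```sh
omegaflux simulate --scenario decay --out demo --seed 1
omegaflux omega --config demo/decay_config.txt
```

## Documentation

See the methods vignette (`vignettes/omegaflux-methods.Rmd`) for the
model, the smoothing and masking parameters, what the synthetic-data
generator does and does not emulate, and known limitations.
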