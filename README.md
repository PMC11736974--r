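# npsamp — nonparametric sampling of times to event

`npsamp` draws times to events from arbitrary hazards for individual-level
simulation models (discrete-event simulation, microsimulation). It is aimed
at modellers in health economics, epidemiology and demography whose event
hazards do not follow a convenient parametric family: life-table mortality,
empirically estimated rates, or hazards driven by time-varying covariates
such as exposure histories — all realizations of a nonhomogeneous Poisson
point process that are awkward to sample by inversion or rejection per draw.

## The method

The hazard is assumed piecewise constant on uniform intervals
[tΔt, (t+1)Δt), t = 0, …, Z, and discretized once into a categorical
distribution over intervals:

    H_t = Σ_{x<t} h_x Δt        (cumulative hazard)
    F_t = 1 − exp(−H_t)         (CDF)
    p_t = F_{t+1} − F_t         (interval probabilities)

Draw the interval index X with P(X = t) = p_t, then return to continuous
time as X_c = X·Δt + Y with Y ~ U[0, Δt), which is exact in distribution
under the piecewise-constant hazard and raises the expected value by
exactly Δt/2. Mass beyond the grid horizon is kept as an explicit residual
category (beyond-horizon draws come back as `NA` sentinels) rather than
silently renormalized.

For a cohort of K heterogeneous individuals the per-individual interval
probabilities stack into a K × (Z+1) row-stochastic matrix and
`sample_multivariate()` draws one interval per row in a single vectorized
pass (one uniform variate per row, inverse CDF on the row's cumulative
probabilities). Proportional-hazards covariate effects — time-independent
or time-dependent, h_i(t) = h_0(t)·m^{x_i(t)} — are applied interval by
interval, with `gaussian_random_walk()` generating per-individual covariate
paths. Parametric baselines (exponential, gamma, log-normal, Gompertz,
both Weibull conventions) come with closed-form means, a survival-integral
oracle and classical direct sampling T = H⁻¹(−log U) as comparators, and
life tables (qx or mx CSVs) convert to hazard grids via h = −log(1 − q).

## A worked example

```r
library(npsamp)

m <- nps(dist_spec("gamma", rate = 0.1, shape = 4), delta_t = 1)
summary(m)
#> Nonparametric event-time sampler (gamma baseline)
#>   grid: 512 intervals of width 1 (horizon 512)
#>   residual beyond-horizon mass: 0
#>   expected event time: 39.5000 uncorrected, 40.0000 corrected

tt <- simulate(m, 1e5, seed = 42)
mean(tt)
#> [1] 40.07247
```

The `summary()` line shows the two deterministic expectations of the
discretized distribution: the mean of the raw interval indices (39.50) and
the continuous-time corrected mean (40.00), which sits on the analytic
gamma mean shape/rate = 40. The simulated mean (40.07) differs from 40.00
only by Monte-Carlo noise (the standard error at n = 10⁵ is ≈ 0.06).

Five scripted workflows pair each estimate with its reference:

```r
run_example(4, n = 1e5, seed = 1)
#> Worked example 4 report (seed 1 )
#>  example       label     n reps mean_uncorrected mean_corrected reference
#>        4 exponential 1e+05    1          8.12015        8.62023   8.55300
#>        4    gompertz 1e+05    1         35.46777       35.96601  35.49926
#>        4  weibull_ph 1e+05    1          8.28752        8.78853   8.27387
```

Example 4 is a proportional-hazards model with the time-dependent covariate
x(t) = t and per-unit hazard ratio 1.02: `mean_corrected` is the sampler's
estimate on a Δt = 1 grid with the hazard frozen at interval starts, and
`reference` is the direct-sampling comparator (exact inversion of the
combined cumulative hazard). The gap between them is the documented
discretization bias of the left-endpoint grid, which shrinks as Δt does.

A thin command-line front end wraps the same functions
(`inst/cli/npsamp convert | sample | example`), reading and writing the
CSV formats documented in `?read_hazard_grid` and `?read_life_table`.

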