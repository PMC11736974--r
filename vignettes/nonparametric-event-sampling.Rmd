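---
title: "Sampling times to event from discretized hazards"
author: "npsamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling times to event from discretized hazards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsamp)
```

## The problem

Individual-level simulation models — discrete-event simulation and
microsimulation in health economics, epidemiology and demography — advance
by drawing times to events. When the hazard of an event is constant the draw
is a textbook exponential; when it follows a standard parametric family the
quantile function does the job. But many hazards of practical interest fit
neither mold: mortality schedules tabulated in life tables, hazards driven
by time-varying covariates such as smoking history or tumour burden, or any
empirically estimated, nonconstant rate. These are realizations of a
nonhomogeneous Poisson point process, and sampling from them usually means
numerical integration or rejection sampling per draw.

`npsamp` implements a different route: discretize the hazard once into a
categorical distribution over time intervals, then draw intervals — cheaply,
in bulk, and for whole heterogeneous cohorts at once — and map the draws
back to continuous time.

## The method

Let $h_t$ be the hazard, assumed piecewise constant on uniform intervals
$[t\Delta t, (t+1)\Delta t)$ for $t = 0, \dots, Z$. The package works down a
chain of exact transformations:

$$H_t = \sum_{x < t} h_x \, \Delta t, \qquad
  F_t = 1 - e^{-H_t}, \qquad
  p_t = F_{t+1} - F_t .$$

The $p_t$ parameterize a categorical distribution over intervals: draw the
interval index $X$ with $P(X = t) = p_t$. A draw is returned to continuous
time as $X_c = X\,\Delta t + Y$ with $Y \sim U[0, \Delta t)$ — under a
piecewise-constant hazard the event is uniformly distributed within its
interval, so this correction is exact in distribution at the grid
resolution, and it raises the expected value by exactly $\Delta t/2$
(the continuous analogue of a half-cycle correction). `expected_time()`
returns the deterministic limit $\sum_t t\,\Delta t\,p_t\;(+\,\Delta t/2)$
that Monte-Carlo means converge to, which the test suite uses as its oracle
throughout.

Writing $H_t$ with the $\Delta t$ factor (rather than a unitless sum) makes
one hazard grid correct on every time scale: a constant hazard $\lambda$
yields $H(t) = \lambda t$ whether the grid is yearly or monthly, and
`rescale_hazards()` converts between scales by multiplying hazards with the
scale ratio while preserving the cumulative hazard over any physical span.

### The residual category

A finite grid leaves mass $1 - F_{Z+1}$ beyond the horizon. Renormalizing
it away silently would bias expected values, so the package carries it as an
explicit residual category: draws landing there come back as a
beyond-horizon sentinel (`NA`), `n_beyond_horizon()` counts them, and means
exclude them (a conditional-on-event mean). `nps(..., renormalize = TRUE)`
opts into the renormalized setting for workflows that assume the event
always occurs by $Z$. By default the automatic horizon extends the grid
until survival falls below $10^{-9}$, so for parametric baselines the
residual is negligible.

### Two discretization routes

For a hazard known in continuous form there are two natural grids, and they
are not interchangeable:

* **`method = "average"`** (default): $h_t = (H((t{+}1)\Delta t) -
  H(t\Delta t))/\Delta t$. Re-accumulation reproduces $H$ at every grid
  point exactly, so the interval probabilities are exact and the only
  discretization effect left is the within-interval placement.
* **`method = "left"`**: $h_t = h(t\Delta t)$. This is the only option when
  the hazard is known pointwise — notably when it is driven by a covariate
  path tabulated at interval starts — and it inherits a bias of order
  $\Delta t$ for steeply changing hazards (it under-resolves an increasing
  hazard, inflating the sampled mean).

The worked covariate examples use `"left"`, because there the hazard is
defined through per-interval covariate values; the parametric examples use
`"average"`. The convergence property checked in the tests — the gap
between the left-endpoint sampler's expectation and the exact mean shrinks
as $\Delta t$ goes from 1 to 0.5 to 0.1 — quantifies the difference. No
criterion is provided for choosing $\Delta t$; that trade-off (resolution
versus grid length) is left to the user.

## Heterogeneous cohorts: the multivariate categorical distribution

When $K$ individuals each have their own hazard (different covariate
histories, different life tables), their interval probabilities stack into a
$K \times (Z{+}1)$ row-stochastic matrix. `sample_multivariate()` draws one
interval per row by consuming exactly one uniform variate per row and
inverting that row's cumulative probabilities — a fully vectorized pass, and
the reason sampling a 100,000-person cohort is a single matrix operation
rather than a loop. The deliberate contract (one uniform per row, inverse
CDF on row cumulative sums, rather than per-category Gumbel tricks) keeps
draws reproducible under a seed and the marginal of every row provably equal
to the univariate sampler's distribution, which the test suite checks by
chi-square comparison.

## Covariates under proportional hazards

Covariate effects multiply the baseline: $h_i(t) = h_0(t)\,m^{x_i(t)}$.
`effect_spec()` makes the coding explicit, because two conventions coexist
in applied work:

* `log_hazard_ratio` (default): $m = e^\beta$, the Cox-model coding;
* `hazard_ratio`: $m = \beta$ itself, a per-unit multiplier (requires
  $\beta > 0$).

The distinction matters numerically: with a covariate growing linearly in
time, reading a coefficient near 1 as a log-hazard ratio multiplies the
hazard by $e^t$ and collapses the event time; reading it as a per-unit
hazard ratio gives the gentle $1.02^t$ growth the worked examples use. The
package validated its `hazard_ratio` reading of the headline covariate
example against the direct-sampling oracle before freezing it (the
log-hazard-ratio reading gives means around 2.4–2.8 for those baselines,
irreconcilable with direct sampling; the hazard-ratio reading agrees to
Monte-Carlo precision).

Covariates are evaluated at each interval's left endpoint and held constant
within the interval, consistent with the method's core assumption.
`gaussian_random_walk()` generates per-individual covariate paths
$y_i(t) = y_i(t-1) + \epsilon_i$, $\epsilon_i \sim N(0, \sigma)$, and
`probability_matrix_from_paths()` turns a baseline plus a bundle of paths
into the sampling-ready probability matrix in one vectorized sweep.

## Parametric baselines and the two oracles

`dist_spec()` names six families (exponential, gamma, log-normal, Gompertz,
and both Weibull conventions). Two Weibull parameterizations are kept
deliberately: the proportional-hazards form $h(t) = k\lambda t^{k-1}$ and
the standard accelerated-failure-time form, because applied examples exist
in both and they are not interchangeable at equal parameter values.

Two independent oracles accompany the sampler:

* `direct_sample()` — the classical inversion $T = H^{-1}(-\log U)$, using
  the family quantile function when no covariate is present and closed-form
  combined cumulative hazards for exponential and Gompertz baselines under
  a linear covariate. Where no closed form exists (Weibull-PH under a
  growing covariate) $H$ is accumulated by composite Simpson quadrature on
  a dense grid (2×10⁵ cells) and inverted by monotone interpolation; the
  inversion error is far below Monte-Carlo noise for smooth hazards. A
  bounded combined cumulative hazard (a defective distribution, e.g. a
  decaying covariate) is reported as an error rather than truncated.
* `numeric_mean_from_hazard()` — $E[T] = \int_0^\infty e^{-H(t)}dt$ by
  adaptive quadrature, with the horizon grown automatically until survival
  drops below $10^{-8}$ and a piecewise partition so the tail is resolved.

Every family passes a three-way agreement check (closed-form mean,
integral oracle, direct-sampling mean) in the test suite.

## Life tables

`read_life_table()` accepts `age` + `qx` (conditional death probability) or
`age` + `mx` (central death rate), with an optional `group` column for e.g.
sex-specific tables. Conversion to a hazard grid uses
$h_x = -\log(1 - q_x)$ — the exact inverse of $q_x = 1 - e^{-h_x}$ under
the within-interval constant-hazard assumption — rather than the crude
$h_x \approx q_x$. The final tabulated age is an open interval; instead of
forcing $F = 1$ there (which would spike the last category), the terminal
hazard is extended to a cap age (default 110) so the residual mass is
negligible for realistic schedules. A `qx` of 1 before the terminal age is
an error (infinite hazard).

`synthetic_life_table()` builds exact tables from a continuous mortality
law — any `dist_spec()` or a Gompertz–Makeham hazard $a e^{bx} + c$ — via
$q_x = 1 - \exp(-\int_x^{x+1} h)$. The default fixture law
$(a = 10^{-4},\ b = 0.09,\ c = 2\times10^{-4})$ is a conventional adult
mortality schedule: exponentially rising senescent mortality on a small
age-independent background, giving a life expectancy near 69 years.
`hazard_scale` multiplies the whole schedule, which is how the grouped
(sex-specific) fixtures are produced (0.9 and 1.1). These fixtures emulate
the *shape* of human mortality but deliberately omit infant mortality, the
accident hump, and tabulation noise — so tests that pass on them validate
the sampling machinery, not any claim about a particular population; real
tables are supplied by the user as CSV.

## What the generator and examples do and do not show

`run_example()` reproduces five canonical workflows (parametric hazards;
homogeneous and heterogeneous life-table cohorts; a deterministic
time-dependent covariate; random-walk covariate paths) with seeded,
desk-scale defaults of $n = 10^4$ draws and 100 repetitions — sizes chosen
so a full report takes seconds while Monte-Carlo standard errors stay well
below the effects being demonstrated; the flags reach larger $n$ when
sharper estimates are wanted. Example 5's covariate strength is not pinned
by any external reference, so the package uses a deliberately small
log-hazard ratio ($\beta = 0.02$) on the random-walk covariate
($\sigma = 0.5$, 100 yearly steps, $y_i(0) = 0$): large enough to make
individuals heterogeneous, small enough that the cohort mean stays in the
vicinity of the baseline Weibull-AFT mean $30.1\,\Gamma(1 + 1/1.3) \approx
27.75$, which is the qualitative check the tests apply. Because its paths
stop at 100 years, example 5 reports a conditional-on-event mean and logs
its beyond-horizon count rather than pretending the horizon is infinite.

## Numerical choices

* Interval convention is half-open $[t\Delta t, (t+1)\Delta t)$ everywhere,
  including the uniform correction $Y \sim U[0, \Delta t)$ — a measure-zero
  difference from the closed interval that keeps the support invariant
  `time` $\in [X\Delta t, (X{+}1)\Delta t)$ exact.
* Negative finite differences of a numerically noisy cumulative hazard are
  clipped to zero when within $10^{-12}$, and are an error beyond that.
* Interval probabilities are normalized at machine precision after
  differencing, so `sum(probs) + residual == 1` holds to $10^{-12}$ by
  construction (property-tested over 1,000 random grids).
* Grids are uniform (a single $\Delta t$); nonuniform grids are out of
  scope.
* Seeding: every sampling function takes an explicit `seed`; the uniform
  correction can be seeded independently of the category draws so corrected
  and uncorrected summaries of the same draws remain pairable.

## Known limitations

* The discretization bias of `method = "left"` grows with
  $\Delta t \times$ (hazard slope); users with steeply rising hazards should
  shrink $\Delta t$ or supply the cumulative hazard and use `"average"`.
* The conditional-on-event mean under residual mass is not the
  unconditional expectation; the residual is reported, not hidden, and it
  is the user's decision how to treat censored-at-horizon individuals.
* Uncertainty in the hazard itself is not propagated; the sampler treats
  the supplied hazard as the mean process. Re-running the (cheap) pipeline
  per resampled hazard is the intended route to probabilistic sensitivity
  analysis.
* Probability matrices are dense: a cohort of $K$ individuals on a grid of
  $Z$ intervals costs $O(KZ)$ memory (about 180 MB for $2\times10^5$
  individuals on a 110-year grid).
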