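---
title: "Invasion probabilities under demographic and environmental stochasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasion probabilities under demographic and environmental stochasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasibility)
```

## The problem

Invasibility is the probability $\Pi_{n \to n_f}$ that a population
starting from $n$ individuals reaches a target abundance $n_f$ before
going extinct.  The mean invasion growth rate $E_r$ — the workhorse of
modern coexistence theory — classifies the extinction state as repelling
or attracting, but it is not a quantitative metric: communities with the
same $E_r$ can have very different invasion probabilities, and
invasibility can even fall while $E_r$ rises.  This package provides two
closed-form probabilities that repair this, together with the procedure
that extracts their inputs from abundance time series and the
individual-based simulators used to validate the whole chain.

Both formulae start from the backward recursion
$\Pi_n = \sum_{\Delta n} W_{n \to n + \Delta n}\,\Pi_{n + \Delta n}$ over
one *dwell time* $\tau$ of the environment (the environment holds a value
for $\tau$ generations, then takes an uncorrelated new one; its
autocorrelation time is therefore $\tau/2$).  The boundary conditions are
$\Pi_0 = 0$ and $\Pi_{n_f} = 1$.  The rare-invader assumption
($n \le n_f \ll N$) makes the per-capita moments abundance-free:

$$E[\Delta n] = \mathcal{E}\,n, \qquad
  \mathrm{Var}[\Delta n] = V_d\,n + V_e\,n^2 ,$$

with $V_d$ the demographic (birth–death) component and $V_e$ the
environmental (community-wide) component.  All parameters here and below
are **per dwell time**.

## The diffusion-approximation formula

Expanding the recursion to second order gives
$E[\Delta n]\,\Pi' + \tfrac12 \mathrm{Var}[\Delta n]\,\Pi'' = 0$, whose
solution with the absorbing boundaries is

$$\Pi^{DA}_{n \to n_f}
  = \frac{1 - (1 + n\mathcal{R})^{Q}}{1 - (1 + n_f\mathcal{R})^{Q}},
  \qquad \mathcal{R} = V_e/V_d,\; Q = 1 - 2\mathcal{E}/V_e .$$

`pi_diffusion()` evaluates this with `nspace_params(eps, Vd, Ve)`.  It is
accurate when selection and fluctuations are weak
($n\mathcal{E}^2 \ll V_d + nV_e$).

## The WKB (large-deviations) formula

For strong noise the increments $\Delta z$ of $z = \ln n$ are not small,
and only $\ln \Pi$ can be assumed smooth.  The jump distribution is
reduced to two destinations $z \pm \beta$ with forward probability
$\alpha$, preserving the first two moments exactly:
$\beta = \sqrt{V_e + E_0^2}$, $\alpha = \tfrac12 + E_0/(2\beta)$, where
$E_0 = E[\Delta z]$ and $V_e = \mathrm{Var}[\Delta z]$ in the outer
(large-$n$) regime.  The nontrivial WKB exponent solves
$1 = 2\alpha \sinh(q\beta) + e^{-q\beta}$, giving
$\bar q = \ln[(1-\alpha)/\alpha]/\beta$, and the outer solution is
$\Pi_{II} \propto e^{\bar q z}$.  In the inner (small-$n$) regime the
dynamics are effectively fixed-environment with exponent profile
$q_{in}(n) = -2E_0 n/V_d$; interpolating
$q(n) = -2E_0 n / (V_d - 2E_0 n/\bar q)$ and integrating yields

$$\Pi^{WKB}_{n \to n_f}
  = \frac{1 - (1 + nR)^{\bar q}}{1 - (1 + n_f R)^{\bar q}},
  \qquad R = \frac{-2E_0}{\bar q V_d}.$$

`pi_wkb()` evaluates this with `zspace_params(E0, Vd, Ve, tau)`;
`wkb_outer()` exposes $(\beta, \alpha, \bar q, R)$.  When $nR \gg 1$ and
$\bar q < 0$ invasion is certain; when $\bar q > 0$ it decays as
$(n/n_f)^{\bar q}$ — only in the window $1/R \ll n \ll n_f$ is
invasibility the binary property that $E_r$ describes.

Note the outer solution form $\Pi_{II} \propto e^{\bar q z}$ is the
standard WKB ansatz for a constant exponent; alternative two-destination
reductions with unequal jump distances exist but are not implemented.

### Relation between the two parameter sets

The n-space and z-space coefficients are *different numerical
quantities*; no automatic conversion is offered.  To second order they
are related by $E_0 = \mathcal{E} - (V_e + \mathcal{E}^2)/2$ (mean log
growth sits below mean relative growth by half the variance).  Under that
correspondence $\bar q \approx -2E_0/V_e$ equals $Q = 1 - 2\mathcal{E}/V_e$
exactly, which is why the two formulae coincide in the weak-noise overlap
regime — the property suite asserts agreement to 2% there.  Plugging the
*same* numbers into both formulae is a category error whenever
$V_e \gtrsim |\mathcal{E}|$.

### Limits and companions

* **Fixed environment** (`pi_fixed_env()`): the Haldane–Kimura form
  $(1 - e^{-2\,g n/V_d})/(1 - e^{-2\,g n_f/V_d})$; both formulae reduce to
  it as $V_e \to 0$, and to $n/n_f$ in the neutral case.
* **Quenched regime** (`pi_quenched()`): when $\tau$ exceeds the invasion
  time, the environment is frozen per attempt and invasibility is the
  state-weighted mean of fixed-environment probabilities.
* **Extinction threshold** (`extinction_threshold()`): $n_{th} = V_d/V_e$,
  the abundance where the two noise sources have equal strength — the
  absorbing boundary that makes infinite-population models quantitative.
* **Natural target** (`natural_target_abundance()`):
  $n_f \sim e^{1/|\bar q|}/R$ for $\bar q < 0$, the abundance above which
  extinction is unlikely.

## Numerical evaluation choices

* Both final formulae are evaluated as
  `expm1(q * log1p(n*r)) / expm1(q * log1p(nf*r))`.  This is free of the
  catastrophic cancellation of $(1+x)^q$ near $q = 0$ (so no series
  switch is needed; only $q = 0$ exactly takes the analytic logarithmic
  limit) and a guard reduces it to `exp(a - b)` when both exponents are
  large.
* $1 - \alpha$ is computed as $V_e / (2\beta(\beta + E_0))$ (and the
  mirrored form for $E_0 < 0$), so $\bar q$ keeps full precision when
  $V_e \ll E_0^2$ instead of dying by subtraction.
* **Negligible environmental variance**: the WKB formula converges to the
  fixed-environment form only logarithmically in $V_e$ (relative
  deviation $\approx R/2 \sim |E_0| / |\ln V_e|$), so both formulae
  branch to `pi_fixed_env()` when $V_e = 0$, $V_e < 10^{-8} E_0^2$, or
  $V_e < 10^{-9}$.  Whenever $V_e$ (hence $R$) is that small the
  interpolation correction $\bar q\, n^2 R^2/2$ is negligible, so the
  branch is numerically continuous.
* Results are clipped to $[0,1]$ only within $10^{-12}$; larger
  violations raise an error (they indicate misuse, not rounding).
* $n$ and $n_f$ are continuous positive reals — the formulae are
  continuum objects; only the simulators use integers.
* `pi_diffusion()` with $V_d = 0$ (pure environmental noise) returns the
  analytic $V_d \to 0$ limit and refuses $n < 1$, where no absorbing
  state exists.

## Inferring the parameters from a time series

The series must be sampled at the dwell time (`thin_series()` helps;
`estimate_dwell_time()` returns $\tau$ as twice the integrated
autocorrelation time of an environmental proxy, summing the empirical
autocorrelation to its first non-positive lag).  Each adjacent pair gives
one transition $(n, \Delta n)$; transitions are pooled into logarithmic
bins (default 12 per decade, at least 50 transitions per bin — abundance
visits are roughly geometric in $n$, so log bins equalise occupancy) and
fitted by weighted least squares with bin-count weights.  The published
procedure leaves binning, weighting and cutoffs open; the defaults here
are choices and are flagged in the report.

* **n-space** (`infer_nspace()`): $\mathcal{E}$ is the zero-intercept
  WLS slope of the binned mean increment on the binned mean abundance;
  $V_d$ and $V_e$ are the intercept/slope of the residual second moment
  divided by $n$, regressed on $E[n^2]/E[n]$ per bin (this regressor
  makes the fit exact under within-bin abundance spread).  Demographic
  jumps are symmetric in $n$, so $\mathcal{E}$ is unbiased even at small
  abundance, and transitions **into** zero are kept.
* **z-space** (`infer_zspace()`): transitions to zero must be dropped
  before taking logarithms; their count is reported.  Conditioning on
  survival inflates the mean and deflates the variance of $\Delta z$
  wherever extinction is actually reachable in one step, so every bin
  losing more than `zero_frac_max` (default $10^{-3}$) of its transitions
  to the filter is excluded from all z-space fits — without this the
  contaminated bins, which carry extreme leverage in $1/n$, corrupt both
  coefficients.  The variance fit
  $\mathrm{Var}[\Delta z] = V_e + V_d/n$ provides the primary $V_d$ and
  $V_e$.  The mean fit $E[\Delta z] = E_0 - V_d/2n$ provides $E_0$ from
  bins above `n_min` (default: five times the crossover
  $V_d/(2|E_0|)$, with the initial $E_0$ guess refined once — the
  all-bins intercept is itself shifted by the small-$n$ bias, so a single
  refinement is needed before the cutoff settles).  A diagnostic
  mean-fit $V_d$ over all usable bins is reported alongside; the two
  $V_d$ routes agreeing within ~10–20% is a useful health check of the
  series.

$E_r = E_0/\tau$ (`invasion_growth_rate()`) connects to classical
invasion analysis.

## The simulators

The update rules are canonical reconstructions of the named models,
isolated behind single step functions so variant schemes can be swapped
without touching inference or formulae.

* **Discrete-time lottery** (`simulate_lottery_discrete()`): per dwell
  step, log-fitness $s = s_0 + \sigma\eta$ with $\eta$ redrawn from a
  unit-variance state distribution (dichotomous $\pm 1$ by default;
  uniform and Gaussian available), $D \sim Bin(N, \min(\tau,1))$ deaths
  split hypergeometrically, each vacancy refilled by the invader with
  probability $p = n e^s/(n e^s + N - n)$.  Dwell periods are
  deterministic of length $\tau$ (consistent with the stated
  autocorrelation-time relation); death fractions cannot exceed 1, so
  $\tau > 1$ is refused — use the Moran variant.
* **Moran lottery** (`simulate_lottery_moran()`): elementary events
  advance time by $1/N$; one uniform death, lottery refill; environment
  redrawn every $\lceil \tau N \rceil$ events.  The Monte-Carlo runner
  samples the Geometric waiting time between *effective* moves (capped at
  environment redraws), an exact acceleration of the same chain.
* **Leslie–Gower trees/saplings** (`simulate_leslie_gower()`): adults
  survive with probability $d$; sapling pools keep a Binomial fraction
  $f$ and gain Poisson recruits at the year's rates; vacancies are filled
  by a sapling-weighted Binomial lottery (with-replacement weighting, so
  promotion does not deplete the pools).  The empirical tropical-forest
  recruitment series the model is usually driven by are not
  redistributable, so `generate_recruitment_series()` supplies a
  synthetic stand-in: correlated lognormal yearly rates with requested
  natural-scale means, log-variance and cross-correlation.
* `lottery_transition_matrix()` builds the *exact* one-step kernel of the
  discrete lottery (states at or above $n_f$ lumped into success), and
  `solve_kolmogorov_exact()` solves the backward linear system — the
  numerically exact oracle that both the formulae and
  `estimate_invasion_mc()` are tested against on small instances.
* `estimate_invasion_mc()` reports the success fraction with a Wilson
  score interval (well behaved near 0 and 1, where invasion probabilities
  live); replicates hitting the event cap (default $10^3 N n_f$
  elementary events) are reported separately, never dropped.

What the generators emulate: fixed community size, dichotomous
environments redrawn on a fixed dwell clock, density independence of the
invader, and (in the Leslie–Gower case) storage through sapling pools.
What they do not: observation error, demographic trends, overlapping
environmental regimes, density dependence near $n_f \sim N$, or more
than two species.  Passing tests therefore validate the method under the
stated model assumptions, not its robustness to messy field data —
observation-error filtering is explicitly out of scope.

## The validation pipeline and its study conditions

`run_comparison()` chains, per grid point: a reflecting-band calibration
run (`calibration_transitions()`; trajectories are re-seeded when they
leave $[1, \text{band}_{hi}]$, the genuine boundary-crossing transitions
are kept, and only the artificial re-seeding jumps are excluded — this
keeps all abundance bins populated without biasing moments), n- and
z-space inference, both formulae at $(n_0, n_f)$, and a Monte-Carlo
measurement.  Every grid point is independently seeded and recomputable.

The default band top $\max(2 n_f, \min(5 n_f, 0.05N))$ keeps calibration
inside the density-independent regime; at $N = 10^4$ and
$n_f = 200$ this is the binding constraint, and community sizes below
$\sim 50\,n_f$ visibly bias the inferred $E_0$ downwards (density
dependence bleeds into the outer regime).  The packaged validation
suites therefore use two desk scales, chosen a priori as the package's
own study conditions: the dwell-time/noise grid
($\tau \in \{0.1, 0.5, 1\} \times \sigma \in \{0, 0.3, 0.6\}$, $s_0 = 0$,
$N = 10^4$, $n_f = 50$, $2\times10^6$ calibration transitions,
$2\times10^4$ Monte-Carlo replicates) and the formula-comparison suite
($N = 10^5$, $n_f = 200$, $4\times10^6$ calibration transitions; weak
noise $\sigma \le 0.1$, $s_0 \le 0.05$ at $\tau = 0.1$, strong noise
$\sigma \ge 0.5$, $s_0 \ge 0.2$ at $\tau = 0.3$).  Parameter-recovery
checks run in the moderate-noise regime $\tau = 0.2$, $s_0 = 0$,
$\sigma = 0.25$.  Monte-Carlo sizes were set from a standard-error
budget (SE $\lesssim 10^{-3}$ wherever a confidence-interval-level
comparison is made); formula-vs-measurement agreement is asserted at the
99% Wilson level so that a handful of simultaneous comparisons keeps a
small overall false-alarm rate.

```{r example, eval = FALSE}
cfg <- lottery_config(N = 1e4, s0 = 0, tau = 0.2, sigma = 0.25)
tr  <- calibration_transitions(cfg, 1e6, model = "lottery",
                               band_hi = 500, n_init = 20, seed = 1)
rz  <- infer_zspace(tr, tau = 0.2)
pi_wkb(1, 200, rz$params)
estimate_invasion_mc(lottery_mc_runner(cfg), 1, 200, 1e4, seed = 2)
```

## Known limitations

* Both formulae assume $n_f \ll N$; neither they nor the inference are
  meaningful when density dependence reaches the calibration band.
* At strong per-dwell selection ($s_0 \gtrsim 0.2$,
  $\tau s_0 \sim 0.1$ per dwell) the two-destination reduction and the
  inner/outer interpolation systematically underestimate
  $\Pi(1 \to n_f)$ even with exact parameters (the validation suite
  shows the WKB error remains well below the diffusion-approximation
  error there, but it is not small).  For quantitative work in that
  regime prefer the exact kernel solver when the state space allows.
* $E_0$ inferred from a finite series is the noisiest input; its error
  propagates into predictions roughly as $2 n_0 \Delta E_0 / V_d$.  The
  n-space $\mathcal{E}$ is far more precise (demographic symmetry), which
  is why the diffusion route can win when data are scarce or confined to
  small abundances.
* Mean times to extinction/invasion, multi-species formulae, and the
  partitioning of $\Pi$ into coexistence mechanisms are out of scope.
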