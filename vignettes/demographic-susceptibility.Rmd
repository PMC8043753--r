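---
title: "Stochastic demographic susceptibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic demographic susceptibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopva)
```

## The question the package addresses

If a species' intrinsic demography makes it fragile — slow reproduction,
late maturity, small populations — then under a shared, escalating stressor
the most demographically susceptible species should be the first to go
extinct. `paleopva` operationalises this idea for communities of large
extinct and extant vertebrates: it builds an age-structured model per
species, degrades each model progressively along several mechanistic axes
(survival, fertility, offtake, catastrophes), summarises the resulting
quasi-extinction risk into one comparable number per species and scenario,
and then asks whether that risk ranking lines up with body mass, generation
length, or an independently estimated extinction chronology.

## The population model

Each species is a female-only, pre-breeding-census Leslie matrix
$\mathbf{M}$ of dimension $(\omega+1) \times (\omega+1)$ over ages
$x = 0,\dots,\omega$:

* first row: effective fertilities $F_x = S_x\, m_{x+1}$ (a daughter is
  censused only if her mother survives the year to produce her; the raw
  $m_x$ can be placed in row one instead via `census = "post-literal"`);
* sub-diagonal: survival probabilities $S_0,\dots,S_{\omega-1}$;
* last diagonal element: $S_\omega$ (a terminal self-loop), or 0 for
  species flagged `terminal_self_loop = FALSE`, which prevents an
  unrealistically old-age-heavy stable structure in taxa with strong
  terminal mortality (wombat-like and dasyurid-carnivore-like life
  histories).

The dominant eigenpair gives the asymptotic growth rate $\lambda$ and the
stable age distribution $\mathbf{w}$ (normalized to sum 1). Generation
length defaults to the mean age of mothers at the stable age distribution,
$$G = \frac{\sum_x x\,\lambda^{-x} l_x m_x}{\sum_x \lambda^{-x} l_x m_x},
\qquad l_x = \prod_{i<x} S_i,$$
with the geometric old-age tail included when the terminal self-loop is
present; $\log R_0 / \log \lambda$ is available as an alternative
(`g_method = "logR0"`). The starting vector is
$\mathbf{n}_0 = A\,D\,\mathbf{M}\mathbf{w}$ with study-zone area
$A = 250{,}000$ km² by default; the extra multiplication by $\mathbf{M}$ is
implemented as stated in the source design, with `premultiply_n0 = FALSE`
to drop it (the two differ only by one deterministic step, i.e. a factor
$\approx \lambda$ in total abundance).

Where the design mixed floor/ceiling notation for horizons and burn-in,
both are read as round-half-up: projections run $40 \times \mathrm{round}(G)$
years and the first $\mathrm{round}(G)$ years are discarded from trajectory
records.

## Stochastic projection

The sampling law (the source design states the models are stochastic
without fixing the law; we use standard PVA practice):

* survivors of age class $x$: $\mathrm{Binomial}(\mathrm{round}(n_x),\,
  S_x s)$, where $s$ is the density-feedback multiplier;
* age-0 recruits: $\mathrm{Poisson}$ with mean equal to the realized
  (feedback-adjusted) first-row contribution $\sum_x F_x s\, n_x$.

The expectation of one step therefore equals the feedback-adjusted
deterministic product, which is what the deterministic mode
(`stochastic = FALSE`) computes exactly — it also skips catastrophe draws,
so it reproduces the plain matrix-power sequence and is used as a test
oracle. Within a year the order of events is: feedback from current total
→ offtake (post-census, before projection) → reproduction and survival →
catastrophe. The engine is compiled (Rcpp) because the acceptance-scale
property runs involve on the order of $10^9$ binomial draws; the R-level
`step_stochastic()` defines the same law and the two are cross-checked.

### Compensatory density feedback

All survival rates are multiplied by
$$s(N) = \frac{1}{1 + c\,(N/K)^\theta},$$
with $K = D \times A$ and $\theta = 1$ (purely compensatory; larger
$\theta$ would approach a ceiling). The strength $c$ is calibrated per
species by root-finding so the deterministic growth rate is exactly 1 at
$N = K$: populations sit at carrying abundance until perturbed. A species
with $\lambda \le 1$ gets $c = 0$ (compensation cannot raise growth) with a
warning. Feedback is calibrated on the *unperturbed* matrix: regulation is
a property of the species, against which perturbations then act.

### Catastrophes

A catastrophe is a rare whole-population binomial thinning by
`cat_severity` (default 0.5, i.e. a ~50% die-off). The baseline frequency
is 0.14 per generation — the published estimate of the incidence of severe
die-offs in vertebrate populations — converted to an annual probability by
dividing by $\mathrm{round}(G)$. Both numbers are configuration fields.

## Perturbation scenarios

Six core scenarios enter the headline risk summaries; two sub-scenarios
are reported separately:

| kind | what is degraded | intensity units | grid |
|---|---|---|---|
| `juvenile_survival` | $S_x$, $x < \alpha$ | proportion | 0–1, step 0.05 |
| `fertility` | all $m_x$ | proportion | 0–1, step 0.05 |
| `all_survival` | all $S_x$ | proportion | 0–1, step 0.05 |
| `offtake` | females removed/yr, apportioned by $\mathbf{w}$ | count | 0 → $N_{stop}$, log-spaced |
| `cat_frequency` | per-generation catastrophe probability | multiplier | 1 → $m_{max}$, log-spaced |
| `cat_magnitude` | catastrophe severity; frequency multiplier drawn $U(1, m_{max})$ per run | proportion | 0.5–1, step 0.05 |
| `offtake_juvenile` (sub) | juvenile removals only | count | as offtake |
| `egg_harvest` (sub, birds) | eggs removed per female-yr | count | 0 → saturation |

$N_{stop}$ and $m_{max}$ are the species-specific intensities at which all
Monte Carlo runs end quasi-extinct, found by a doubling search plus
geometric bisection (`find_saturation_intensity()`). Drawing the
catastrophe-frequency multiplier uniformly from $[1, m_{max}]$ inside the
magnitude scenario standardises relative risk across species and
guarantees some extinctions at every severity. Offtake removals happen
post-census, pre-projection — the removed females do not breed that year.

For egg harvest, the harvestable pool is the egg-production component of
total fecundity: the egg fraction is nest success × hatching probability
for the emu-like reference (0.406 × 0.419 ≈ 0.17); removing $e$ eggs per
female-year removes $\min(e/2, \text{daughter-egg pool})$ daughters at a
1:1 sex ratio, never driving fertility negative.

Quasi-extinction is scored on the **final** total: a run is quasi-extinct
when its last projected female total is below $E_q = 50$ (the
inbreeding-depression floor; 100 total individuals at 1:1 sex ratio). A
first-passage variant (`first_passage = TRUE`) scores the post-burn-in
minimum instead and is off by default.

## Risk synthesis

Each species × scenario sweep yields a quasi-extinction curve
$\Pr(E_q)(x)$; its trapezoidal integral on the min–max-normalized
intensity axis is the scenario-specific risk in $[0,1]$ (the raw-axis
integral is also stored; normalization makes cross-scenario sums
unit-free). Within each scenario, species are ranked by integral
(1 = most resilient, ties averaged); the median of the six core-scenario
ranks is the single susceptibility index, and the sum of the six core
integrals is the total risk. Sub-scenarios never enter the total or the
median.

Common random numbers couple consecutive grid points: the configured seed
is re-applied at every intensity, so risk curves are monotone up to
residual Monte Carlo noise; tests allow violations only within three
binomial standard errors.

## Regression machinery

`fit_allometry()` is ordinary least squares of risk on $\log_{10}$ mass or
$\log_{10} G$, with the evidence for a relationship expressed as the AICc
weight ratio of the slope model versus the intercept-only model
($ER = \exp\{(\mathrm{AICc}_0 - \mathrm{AICc}_1)/2\}$). The small-sample
correction is mandatory at $n \approx 21$; ER is reported as `NA` below
$n = 5$ where AICc is undefined. `chronology_concordance()` computes the
Spearman correlation (plus OLS with the same ER machinery, and an optional
permutation p-value) between a risk measure and extinction-window
midpoints, with earliest/latest-bound sensitivity fits;
`outlier_sensitivity()` refits with named species removed.

## The synthetic world

The real demographic table behind the original analysis is not printed in
the available sources, so the package ships a generator that emulates its
*structure*: 21 species (13 extinct, 8 extant) in five functional groups,
masses from ~2 kg to ~3 t, and internally consistent near-stationary life
histories. All parameter choices were made once, from standard scaling
arguments, and are exposed in `generator_spec()`:

* generation length $G = 2.2\, M^{0.25}$ (birds 2.0, monotremes 3.2 —
  giving slow giant-bird and long-lived monotreme profiles), lognormal
  jitter 5%;
* $\alpha = \mathrm{round}(0.45\,G)$, $\omega = \mathrm{round}(2.6\,G)$;
* adult survival $1 - 0.4\,M^{-0.2}$ (clamped to $[0.35, 0.97]$),
  juvenile survival 75% of adult;
* density $D = 40\, M^{-0.75}$ individuals km⁻² (Damuth-type slope; the
  coefficient makes the smallest carrying abundance a few tens of
  thousands at $A = 250{,}000$ km², so the least abundant species still
  start in the thousands);
* maximum growth rate $r_{max} = 0.45\, G^{-1.4}$, so
  $\lambda = e^{r_{max}}$ clamped to $[1.005, 1.095]$: fast small species
  rebound quickly, slow giants barely exceed replacement, and *per
  generation* recovery $r_{max} G \propto G^{-0.4}$ also declines with
  slowness (maximum lifetime output falls as life histories slow). The
  fertility level is then calibrated by root-finding so the deterministic
  $\lambda$ hits this target exactly — fertility is an allometric
  consequence of mass, not a free draw;
* the heaviest species per group are flagged extinct (4/5/1/2/1); the
  smallest vombatiform and two mid-sized carnivores lose their terminal
  self-loop.

Extinction windows are generated in a chosen truth regime —
`risk_ordered` (susceptible species die first), `mass_ordered`, or
`random` (the no-pattern regime) — which makes the chronology test
testable in both directions.

What a green test on this world does establish: the whole pipeline —
matrix construction, stochastic engine, feedback calibration, sweeps,
integrals, ranks, regressions — behaves correctly and recovers
relationships that are built in. What it does not establish: anything
about the real fauna's parameter values, which enter only as data.

## Numerical choices

* Round-half-up everywhere a generation count becomes an integer.
* Modulus-tied (cyclic) dominant eigenvalues: take the candidate with the
  largest positive real part and average $\mathbf{w}$ over one cycle of
  the power iteration.
* $R_0$ from the fundamental matrix $\mathbf{F}(\mathbf{I}-\mathbf{T})^{-1}$
  (exact under the terminal self-loop); $R_0 = 0$ short-circuits when the
  fertility row is zero, and an immortal transition structure returns
  `Inf` rather than failing.
* Saturation searches: doubling then geometric bisection to 10% relative
  tolerance; "certain extinction" means every run in the (smaller) search
  sample is quasi-extinct.
* Binomial sizes are `round(n)`; populations are propagated as doubles.
* A perturbation that zeroes the entire matrix (e.g. 100% survival
  reduction) is handled as deterministic one-step extinction rather than
  as a degenerate eigenproblem.

## Known limitations

* Aspatial, single-population models; no biotic interactions.
* The demographic-stochasticity law (binomial/Poisson) and the feedback
  form are conventional choices where the source design is silent; both
  are documented switches rather than claims.
* Vital-rate uncertainty is not resampled per iteration (the optional
  rate-jitter of the original design is out of scope here).
* In the default synthetic world the catastrophe-magnitude scenario's
  risk is *slightly* better predicted by mass than by generation length:
  carrying abundance $K = D A$ is tied to mass with only 5% scatter, and
  that population-size gradient outweighs the generation-linked recovery
  gradient. A real fauna has 1–2 orders of magnitude of density scatter,
  which would weaken the mass link; the generator default was chosen
  before this comparison was run and is deliberately left unchanged, so
  the corresponding acceptance check is an honest red rather than a tuned
  green (see `tests/testthat/test-acceptance.R`, criterion 7b).
* Quasi-extinction on the final total (not first passage) means a run
  that dips below $E_q$ and recovers counts as surviving; the
  first-passage alternative is one flag away.
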