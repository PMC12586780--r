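---
title: "Modelling body-temperature controllability in regionally endothermic fishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling body-temperature controllability in regionally endothermic fishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofin)
```

## The scientific problem

Tunas, billfishes and lamnid sharks with regional endothermy keep parts of
their body — typically the slow-twitch red swimming muscle — warmer than the
surrounding water using vascular countercurrent heat exchangers. Beyond
simply elevating muscle temperature, some of these species appear to
*control* their heat-exchange rate: warming quickly in the warm mixed layer
and cooling slowly below the thermocline, which prolongs foraging time at
depth and shortens recovery time at the surface. `thermofin` provides the
analysis chain needed to quantify that controllability from animal-borne tag
records, and to compare it across species in a phylogenetically informed
way.

## The heat-exchange model

The whole-body heat budget is Newtonian. With muscle temperature $T_b$,
ambient water temperature $T_a$ and time in minutes,

$$\frac{dT_b}{dt} = k\,\big(T_a(t) - T_b(t)\big) + \dot{T}_m,$$

where $k$ (1/min) is the whole-body heat transfer coefficient — the rate of
body-temperature change per degree of body–ambient difference — and
$\dot{T}_m$ (°C/min) is the internal (metabolic) heat production rate,
treated as constant, which is reasonable for animals cruising at steady
speed. Two variants are fitted:

* **constant k**: a single coefficient throughout (2 mean parameters);
* **two-regime k**: $k = k_\mathrm{warm}$ while $T_a \ge T_b$ (warming
  phase) and $k = k_\mathrm{cool}$ while $T_a < T_b$ (cooling phase)
  (3 mean parameters).

A large $k_\mathrm{warm}/k_\mathrm{cool}$ ratio is the signature of active
modulation of the heat exchangers. The regime switch is keyed to the
*simulated* muscle temperature, so prediction is a closed forward simulation
from a single initial value (the first observation) and never peeks at the
data; keying to the observed trace is available (`regime = "observed"`) as a
sensitivity check, since the original formulation does not say which was
used.

### Discretisation

The data are at 1-min resolution and the model is a continuous ODE, so a
discretisation must be chosen. The default is forward Euler at
$\Delta t = 1$ min, which is stable for $k\,\Delta t < 1$ (the fitted
coefficients are two orders of magnitude below that). An exact exponential
step — integrating the ODE analytically over each interval with $T_a$ held
constant — is provided (`scheme = "exact_step"`); the two agree at first
order in $\Delta t$, and the exact step is the right choice for coarse steps
or $k$ near the bound. Under the Euler scheme the fitter caps the upper
bound of $k$ just below $1/\Delta t$ so the optimizer cannot enter the
unstable region.

### Fitting and model selection

`fit_heat_model()` minimises the residual sum of squares with bounded
Levenberg–Marquardt (minpack.lm), all parameters starting at 0.01 inside
$[0, 1]$. On non-convergence, five deterministic rescalings of the starting
point are tried before erroring. A series in which $T_a$ and $T_b$ coincide
throughout carries no information about $k$ and is rejected as degenerate.

Model selection uses AIC together with a mean-absolute-error guard. The AIC
convention is the Gaussian least-squares form
$n\log(\mathrm{RSS}/n) + 2(p+1)$, counting the error variance as a
parameter; since the original convention is unreported, only AIC
*differences* are meaningful and no attempt is made to match published AIC
magnitudes. The two-regime model nests the constant model, so it almost
always wins on AIC; when its relative MAE improvement is below 10%
(configurable) the extra coefficient is judged to be fitting noise and the
constant model is kept, with the guard decision recorded. This reproduces
the qualitative judgement that near-identical fitting errors indicate
overfitting in the least vertically active individual.

## Thermocline and dive segmentation

The vertical temperature structure is estimated per deployment: ambient
temperature at 1-min resolution is grouped into 1-m depth bins, per-bin
means are taken, empty interior bins are filled by linear interpolation
between neighbouring bin means (animals do not occupy all depths uniformly;
the fill count is reported), and the bin means are smoothed with a centred
moving average spanning ±10 m. The symmetric window was chosen because an
asymmetric (even or trailing) window displaces a linear profile by half a
bin and biases the gradient location; a centred ±10 m span is the symmetric
reading of a "20-m moving average".

The thermocline is the depth of the steepest gradient of the smoothed
profile, by first differences of adjacent bins. Smoothing turns a sharp
interface into a ramp of *exactly tied* gradient pairs, so the detector
takes the shallowest maximal-gradient run and returns its central depth:
for a sharp step this recovers the interface itself, for a smooth sigmoid
the unique steepest pair, and for a fully linear (everywhere-tied) profile
the centre of the profile. Detection is invariant to additive temperature
offsets and to uniform changes in depth-coverage density.

Dives are maximal runs of samples strictly deeper than the thermocline.
Runs lasting ≤ 10 min are excluded (the cutoff is inclusive); separate runs
are never merged, so a brief excursion above the thermocline splits a dive
— the simplest reading, since no merging rule is documented for the original
analysis.

Preprocessing follows the tag-analysis conventions: the first 6 h of each
record are dropped to remove capture effects (time re-zeroed by default),
profiles use 1-min data, and the model fitter uses 1-min *subsampled* (first
sample per interval) rather than block-averaged data; both resampling modes
are available.

## The synthetic-data generator

Every downstream stage is testable without any downloads because the `synth`
functions generate data with exactly the structure the analysis assumes:

* **Water column**: a logistic (sigmoid) depth–temperature profile, default
  25 °C mixed layer over 14 °C deep water with thermocline depth 100 m and
  10 m half-width — typical of the subtropical water columns in which these
  sharks were tagged. The logistic form is an artifact choice, not a claim
  about any study site: its steepest gradient sits exactly at the nominal
  thermocline depth, giving segmentation tests an analytic truth.
* **Dive tracks**: trapezoidal dives (constant-rate descent, flat bottom,
  constant-rate ascent) separated by surface intervals. This keeps
  below-thermocline crossings countable by construction. Depth-bin coverage
  of the transition zone depends on how often and how slowly the track
  crosses it; profile-oriented simulations therefore use many dives at
  varied depths with vertical rates of 10–20 m/min, which occupies nearly
  every 1-m bin, while model-fitting simulations use a simpler 3-dive
  schedule.
* **Muscle traces**: the forward heat-exchange simulation plus i.i.d.
  Gaussian sensor noise (default SD 0.1 °C) on the muscle channel only; the
  ambient channel is treated as exact since sensor noise matters most on the
  fitted channel. A single integer seed drives all draws (noise is one
  `rnorm` call after `set.seed`), so deployments are bit-reproducible.
* **Comparative tables**: per-individual coefficients generated on the
  log10 scale as group-specific allometric lines (defaults are the published
  group fits, e.g. $k_\mathrm{warm} = 0.11\,M^{-0.21}$ for endotherms) plus
  a Brownian phylogenetic species effect (SD 0.15), an i.i.d. species
  effect (SD 0.10) and individual residuals (SD 0.10), three individuals
  per species, with masses log-uniform over 0.01–1600 kg — the span of the
  published compilation. The variance scales are set once at values typical
  of log-scale physiological rate data.

What the generator does **not** emulate: behavioural realism (no speed or
acceleration channels, no yo-yo microstructure), solar heating at the
surface, pre-dive anticipatory warming, measurement error in digitised
literature values, or depth-dependent noise. Passing tests therefore
demonstrate that the estimators recover the truth *under the model's own
assumptions*; they do not certify behaviour on records that violate them
(the anticipatory-warming episode seen in one tagged shark is exactly such
a violation, visible as structured residuals rather than something the
model can track).

## The phylogenetic mixed model

The comparative question — do endotherms and ectotherms scale differently? —
is answered with a Gaussian mixed model on $y = \log_{10} k$:

$$y = X\beta + u + s + \varepsilon,\qquad
u \sim N(0, \sigma_p^2 A),\quad s \sim N(0, \sigma_s^2 I),\quad
\varepsilon \sim N(0, \sigma_e^2 I),$$

with fixed effects up to $\log_{10}\mathrm{mass} \times \mathrm{endothermy}$,
a phylogenetic species effect with Brownian covariance $A$, and an i.i.d.
species effect for intraspecific replication. $A$ comes from the tree with
Grafen branch lengths (node height = descendant tips − 1, scaled to unit
root height), the standard choice when only topology is trustworthy; after
scaling, $A$ has unit diagonal so $\sigma_p^2$ is directly comparable to the
other variances. The ratio response $k_\mathrm{warm}/k_\mathrm{cool}$ is
formed per individual before the log transform.

Because the response is Gaussian, every full conditional is closed-form and
the model is fitted by a blocked Gibbs sampler (written in C++): draws of
$\beta$, $u$, $s$ and the three variances cycle with conjugate
normal/inverse-gamma updates. Priors are weakly informative — $N(0, 10^8)$
on coefficients, inverse-gamma(0.001, 0.001) on variances — since the
original analysis reports none; they are configurable. The default chain is
20,000 iterations with 2,000 burn-in and thinning 20 (900 retained draws),
which this conjugate sampler mixes through easily; the longer run lengths
used in published comparative work (500,000 / 50,000 / 500) are available
via `mcmc_settings()`.

Model ranking uses the conditional-deviance DIC,
$\mathrm{DIC} = \bar{D} + p_D$ with $p_D = \bar{D} - D(\bar\theta)$, the
deviance evaluated conditionally on the random effects (random effects "in
focus", the common GLMM convention); this is an approximation to whichever
convention the original software used, so DIC *differences* between
formulas, not magnitudes, are the meaningful output. Group-level allometric
lines extracted from the posterior means feed `predict_k_at_mass()` and
`contrast_at_mass()`, which report fold differences at a reference mass in
the direction each contrast is conventionally quoted: endotherm/ectotherm
for warming rate and for the warming:cooling ratio, ectotherm/endotherm for
cooling rate. At the 140-kg reference mass — the largest endotherm in the
published compilation — the published lines give fold differences of 2.9,
2.0 and 7.4 respectively:

```{r contrasts}
pub <- published_allometry()
sapply(c("k_warm", "k_cool", "ratio"), function(r)
  signif(contrast_at_mass(pub[pub$response == r, ], 140, r), 2))
```

## Numerical choices and degenerate inputs

* Euler instability ($k\,\Delta t \ge 1$) raises an error pointing to the
  exact step; the fitter caps bounds pre-emptively.
* A perfect fit (RSS = 0) yields an AIC of $-\infty$, flagged so selection
  logic can recognise it.
* Thermocline detection requires ≥ 21 smoothed bins and ≥ 30 m of depth
  coverage; an all-constant profile raises "no gradient".
* Empty-bin interpolation happens before smoothing and is counted.
* The trapezoid generator rejects dive schedules that exceed the deployment
  duration, naming the overflow.
* `tag_series` requires strictly increasing time and records the modal
  step; strict step uniformity is enforced by the operations that need it,
  so a record with isolated dropped rows can still be read.
* Retained MCMC draws are $(\mathrm{iterations} - \mathrm{burnin}) /
  \mathrm{thin}$; DIC requires at least 100 of them.

## Problem sizes

The test-suite and analysis-script simulations use 22–28 h deployments at
1-min resolution (1,320–1,680 samples), 20-seed replication for recovery
properties, 25-species comparative datasets with 3 individuals per species,
and the 20,000-iteration default chains. These sizes were chosen so the
full verification cycle runs in well under a minute per stage while leaving
estimation error far smaller than the tolerances being checked.

## Known limitations

* $\dot{T}_m$ is constant; time-varying heat production (burst swimming,
  digestion) is out of scope.
* The heat model cannot represent heat retention *against* the gradient
  (muscle warming above ambient at depth); such episodes appear as
  structured residuals.
* Dive merging across brief thermocline excursions is not implemented.
* The DIC and AIC conventions are documented package choices; compare
  differences, not magnitudes, against other software.
* No tree inference and no measurement-error model for literature-digitised
  coefficient estimates.
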