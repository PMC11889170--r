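---
title: "Reduced-order models of amyloid aggregation and physics-informed rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order models of amyloid aggregation and physics-informed rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romkin)
```

## The modelling problem

Amyloid-beta aggregation proceeds from free monomer through oligomeric
intermediates to mature fibrils.  A fully granular kinetic description
tracks every oligomer size and is hopeless to identify from the data that
experiments actually produce — typically fluorescence time courses that
report aggregated mass at a handful of initial monomer concentrations.
`romkin` works with a family of *reduced-order* models in which ranges of
aggregate sizes are pooled into species bins.  Every model in the family is
a linear chain of reversible condensation steps under mass-action kinetics:
step $i$ converts $k_i$ units of bin $i$ into one unit of bin $i{+}1$,

$$
\frac{d[\mathrm{bin}_i]}{dt} \mathrel{+}= k_i\,\big(\beta_i\,[\mathrm{bin}_{i+1}]
  - \alpha_i\,[\mathrm{bin}_i]^{k_i}\big), \qquad
\frac{d[\mathrm{bin}_{i+1}]}{dt} \mathrel{+}= \alpha_i\,[\mathrm{bin}_i]^{k_i}
  - \beta_i\,[\mathrm{bin}_{i+1}],
$$

with forward (aggregation) rate $\alpha_i$ and backward (dissolution) rate
$\beta_i$.  In the stored parameter vector these are interleaved as
$\beta_i = a_{2i-1}$, $\alpha_i = a_{2i}$.  Eight binning structures are
defined, from the maximally reduced two-bin Model 1 (one reversible
reaction, pre-nucleation mass versus fibril) to the fully granular five-bin
Model 8 (eight rate parameters).  They form a lattice ordered by
refinement: each edge splits one bin in two, either on the pre-nucleation
side (a *primary* unpacking) or the post-nucleation side (*secondary*).

Two structural facts follow from the chain construction and are enforced
and tested throughout:

* **Mass conservation.** Weighting bin $i$ by the cumulative product of the
  reaction orders below it (first bin weight 1) yields a vector $w$ with
  $w \cdot f(x) = 0$ for every state and parameter set, so total
  monomer-equivalent mass is invariant.
* **Boundary positivity.** With nonnegative rates, an empty bin has
  nonnegative net flux, so trajectories from nonnegative initial states
  stay nonnegative (up to solver tolerance).

The reaction orders $n, m, s, c, p$ are not fixed by theory; they default
to 2 (a dimerization-like choice) and are configurable per model.
Coarse-to-fine comparisons pool bins in monomer equivalents
(`collapse_trajectory()`, `rebin_dataset()`): a coarse bin is the
mass-weighted sum of its constituent fine bins divided by its own weight,
which preserves total mass exactly at every time point.

## Synthetic data

`generate_dataset()` emulates the observation design the estimators are
meant for: five aggregation time courses started at 1, 1.4, 2, 3 and 5 µM
monomer, each observed at 200 uniformly spaced times, with additive
Gaussian noise and optional masking so that only the terminal fibril bin is
seen (the fluorescence situation).  Design choices the data source leaves
open were fixed once:

* all initial mass sits in the smallest bin (concentration in µM); other
  bins start at zero;
* the time axis is unitless with `t_end = 100` by default;
* noise is additive Gaussian on concentrations (`noise_sd`, default 0 for
  oracle experiments, 0.01–0.02 in the stochastic experiments below), with
  an optional truncation at zero;
* normalization is per-species maximum by default; a `global_max` mode
  divides everything by one factor, which preserves relative amplitudes
  across experiments and is what the reduction workflow uses for
  fibril-only data.

What the generator deliberately does **not** emulate: the photophysics of
thioflavin-T fluorescence (baseline drift, quenching, saturation
nonlinearity), stochastic kinetics at low copy number, and seeded or
off-pathway aggregation routes.  Passing tests on this generator therefore
demonstrate correctness of the estimation machinery under the stated noise
model, not robustness to instrument artefacts.

## The physics-informed fit

`fit_rom()` estimates rates by training one small multilayer perceptron per
experiment — by default three hidden `tanh` layers of width six — mapping
(scaled) time to all species concentrations, jointly with a single shared
rate vector.  Sharing the rates across experiments makes this a global fit:
every initial concentration constrains the same kinetic parameters.  The
loss is

$$
\mathcal{L} \;=\; w_d\,\underbrace{\tfrac1n \textstyle\sum_t
(Y_t - \hat Y_t)^2}_{\text{data}} \;+\;
w_p\,\underbrace{\tfrac1n \textstyle\sum_t \big|\,d\hat Y_t/dt -
f(\hat Y_t;\,a)\,\big|}_{\text{physics}},
$$

with $w_d = w_p = 1$ by default, trained with Adam (learning rate 0.001,
35,000 epochs by default).  The physics residual uses the *exact* time
derivative of the surrogate, obtained by propagating derivatives through
the network alongside the activations; the reverse pass differentiates both
paths, so rate-parameter and weight gradients include the second-order
terms this introduces.  Gradients are verified against finite differences
in the test suite.  A *literal* physics mode — the pointwise difference
$|f(Y_t) - f(\hat Y_t)|$ — is also provided; it is not the default because
it vanishes whenever the surrogate matches the data, regardless of the
rates, and so cannot identify them on its own.

Numerical choices that matter, each fixed after the problem structure was
understood and documented here rather than tuned per dataset:

* **Initial-condition constraint.** The surrogate is parameterized as
  $\hat Y(t) = y_0 + g(t)\,(s \odot N(t))$ with
  $g(t) = 1 - e^{-\tau/\tau_0}$, which pins $\hat Y(0) = y_0$ — essential
  when only the fibril bin is observed, since nothing else anchors the
  hidden bins.  The range parameter $\tau_0$ is set from the data as the
  median time for an observed series to cover 63% of its total change.  A
  saturating $g$ is used instead of the plain factor $t$ because the latter
  forces the network output to spike near $t = 0$ for fast transients,
  which a small `tanh` network approximates very slowly.
* **Input warping.** The network input is
  $\log(1 + \tau/\tau_0)/\log(1 + 1/\tau_0)$ rather than raw scaled time
  $\tau$, spreading a fast early transient over a usable share of the input
  range; the chain rule through the warp keeps the collocation derivative
  exact.
* **Output scaling.** Each output is scaled by the species' observed
  magnitude (or an initial-mass bound for unobserved bins), so weights stay
  $O(1)$ across concentration scales.
* **Rate parameters** are initialized uniformly in $[0.01, 0.5]$ under the
  run seed and trained with a 10-fold larger step size than the weights;
  they receive far smaller gradients, and a shared step leaves them
  crawling long after the trajectories are fitted.  Negative estimates are
  permitted (small negative backward rates do occur in practice); an
  optional softplus constraint enforces positivity.
* The five experiments enter the loss pooled and unweighted; loss weights,
  warmup and learning-rate decay are configurable but default to off/1:1.

Determinism: all stochastic initialization derives from the config seed,
and training is a fixed sequence of floating-point operations, so a fit is
bit-reproducible from its configuration.

## The least-squares baseline and identifiability

`fit_least_squares()` is the classical alternative: Levenberg–Marquardt on
the residuals between integrated trajectories (deSolve, `lsoda`) and the
observations.  It is fast and sharp near a good start and serves three
roles: the comparison baseline, the refinement stage of the reduction
workflow, and the re-optimizer inside profile likelihood.

`profile_likelihood()` steps one rate over a grid — 21 points, log-spaced
over [MLE/10, MLE·10] for positive estimates, linear otherwise — and
re-optimizes all other rates at each value, warm-starting from the
neighboring solution and keeping a restart from the global optimum if it
does better.  The observation noise scale is unknown and is profiled out
analytically (concentrated Gaussian likelihood); a fixed-sigma mode exists.
The 95% interval is where the profile stays within
$\chi^2_1(0.95)/2 \approx 1.92$ of its minimum, with threshold crossings
located by linear interpolation; a side that never crosses inside the grid
is reported unbounded.  A parameter is called *identifiable* when both
endpoints are interior and the interval spans fewer than two decades.
Profiles are computed against the integration-based objective, never the
neural surrogate, so the intervals do not inherit surrogate approximation
error.

## Automatic reaction-order reduction

`run_reduction()` answers: what is the coarsest binning the data support?
It fits Model 1 first, then repeatedly fits the current model's successors
in the lattice — primary unpackings first, then secondary — and advances to
the best successor only if it improves the fit by more than an absolute
threshold (default 0.005 in normalized units), otherwise it backtracks and
stops that phase.  The workflow never leaves the lattice and never revisits
a model; the full audit trail (every fit, metric and decision) is returned.

Two design questions the workflow description leaves open were resolved as
follows:

* **What counts as the residual of a candidate model.** The surrogate's own
  training MAE cannot arbitrate between mechanisms: given enough epochs,
  *any* candidate's network tracks the data, because the data loss rewards
  that directly.  The decision metric is therefore mechanistic — the mean
  absolute residual of integrated trajectories at the candidate's fitted
  rates.  With the default `polish = TRUE`, each candidate's rates are
  refined by a short Levenberg–Marquardt pass started from both the neural
  estimate and a fresh default start (the better of the two by SSE wins),
  so the metric reflects the model rather than the optimizer's state.  Both
  the mechanistic and the surrogate MAE appear in the audit trail.
* **Identifiability gate.** Profiles of the two rates introduced by the
  winning refinement are computed and logged (advisory mode); in strict
  mode a successor whose new rates are non-identifiable is inadmissible.
  Advisory is the default because fit improvement and identifiability are
  stated as joint criteria without precedence.

All successors at a step are fitted and the best admissible one taken
(beam width 1); a greedy first-improving mode exists for speed.  An
AIC-style penalized criterion is available as an alternative to the raw
MAE threshold but is not the default.

`compare_models()` ranks fits by MAE with ties (within tolerance) broken
toward fewer parameters.  `timescale_sweep()` regenerates and refits at
several sampling densities and tabulates per-model MSE, each model's column
normalized by its own maximum — the scaling-robustness analogue of a
fit-versus-timescale table.

## Problem sizes used in the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) run
on deliberately moderate sizes, chosen so the full battery completes on a
single CPU while leaving the conclusions unchanged: parameter-recovery
experiments use the full design (5 concentrations × 200 points, all bins
observed, noiseless) with default training; the profile-coverage experiment
uses 20 replicates of a 2-experiment, 40-point design at noise 0.02; the
reduction-selection experiments use 100-point fibril-only data with
3,000-epoch neural fits plus refinement over 5 seeds per scenario; the
density sweep compares 50 against 200 points for all eight models.

## Known limitations

* Rates are point-identified per model; no joint uncertainty across the
  model choice is propagated.
* The profile re-optimizer is a local method with warm starts and one
  restart; for badly multimodal likelihoods the profile can be
  optimistic (too narrow) at points where re-optimization stalls.
* With fibril-only data, hidden-bin trajectories are constrained only
  through the ODE residual and the initial condition; their absolute
  scales are weakly determined, which is visible as wide profile
  intervals for pre-nucleation rates.
* The literal physics mode is provided for completeness but is not a
  usable estimator on its own (see above).
* Reaction orders are treated as fixed configuration; learning them
  jointly with the rates is out of scope.
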