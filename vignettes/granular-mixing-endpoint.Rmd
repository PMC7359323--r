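---
title: "From particle contacts to mixing-time surrogates: the granumix methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From particle contacts to mixing-time surrogates: the granumix methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granumix)
```

## The problem

Drying a crystallized drug substance in an agitated filter dryer (AFD)
requires intermittent agitation so the cake heats uniformly, but over-mixing
causes attrition and agglomeration. The design question is therefore *how
long to agitate until the bed is uniformly mixed*. Direct simulation of a
production dryer by the discrete element method (DEM) is infeasible
(real cakes contain upward of 10^12 particles), and even scaled-down DEM runs
are expensive because the stable time step is microseconds.

`granumix` implements a three-stage ensemble strategy at desk scale:

1. a soft-sphere **DEM engine** simulates a labelled, cohesive particle bed
   stirred by a rotating blade and emits trajectory snapshots;
2. the **segregation index** psi quantifies mixing from inter-particle
   contacts, and an **ARIMA** stage fits the observed psi(t) and forecasts the
   time `T_end` at which psi first reaches the uniform-mixing cutoff
   (1.1 by default), so the simulation can stop long before mixing completes;
3. a **surrogate** stage learns `T_end` across the nine material/process
   descriptors and ranks them by permutation importance.

Every stage can also be exercised without DEM through synthetic generators,
which is how most of the test suite runs.

## The DEM contact model

Particles are monodisperse spheres with radius `R`, density `rho`, and mass
`(4/3) pi R^3 rho`. The contact force between overlapping spheres (overlap
`delta`) is Hertz-Mindlin with a simplified-JKR cohesive term:

* normal elastic: `F_n = (4/3) E* sqrt(R*) delta^{3/2}`, with effective
  modulus `E* = E / (2 (1 - nu^2))` and effective radius
  `R* = R_i R_j / (R_i + R_j)`;
* normal dashpot: `-2 sqrt(5/6) beta sqrt(S_n m*) v_n` with
  `S_n = 2 E* sqrt(R* delta)` and the damping ratio
  `beta = ln e / sqrt(ln^2 e + pi^2)` derived from the restitution
  coefficient `e`. The dashpot is left unclamped: the brief tensile phase at
  the end of a collision is part of the calibration, and the two-body test
  recovers `e` to well under 1%;
* tangential: a Mindlin spring with per-contact history
  (`S_t = 8 G* sqrt(R* delta)`), capped by the Coulomb limit `mu_f |F_n|`;
* cohesion: `F_coh = gamma_cohesion * pi delta R*`, the "cohesive energy
  density" parameterization in which an attractive force scales with the
  contact area;
* gravity; no liquid bridges, electrostatics, breakage or polydispersity.

Vessel and blades are kinematic boundaries of the same material: a flat
floor, a cylindrical wall, and (by default two) flat vertical blades spanning
the radius, rotating about the axis at the impeller speed. Blade contacts use
the blade's rigid-body surface velocity, which is how momentum is pumped into
the bed. Integration is velocity-Verlet with particle spin; rolling friction
is omitted (it is not among the varied parameters). The default time step is
0.2 of the Rayleigh critical time computed from `E`, `rho`, `R`; larger
values are rejected, and a diverging run aborts with an instability error
naming the offending `dt` after flushing the partial trajectory.

Beds are initialized on a jittered lattice, settled under gravity with the
blade at rest, and then split into two vertical half-beds at the axis plane
(the plane through the median x, so label counts differ by at most one).
Determinism is strict: identical parameters and seed give bitwise-identical
trajectories.

### Desk-scale study conditions

The default conditions were chosen once to represent a desk-scale AFD:
`N_p = 2000` spheres of `R = 3 mm`, `rho = 1100 kg/m^3`, `e = 0.6`,
`mu_f = 0.1`, `gamma_cohesion = 1e4 J/m^3`, `E = 5e6 N/m^2` (a standard
DEM softening; production-scale studies of this system use the same value at
their largest runs), vessel radius 5 cm, two blades of height 2.5 cm,
fill level 9 cm, 60 RPM, 3 s of agitation sampled every 20 ms. At 60 RPM a
few seconds already cover several impeller revolutions, and mixing is
revolution-driven. Reference runs take roughly two minutes on one CPU.

A physical caveat that matters for forecasting: with a bottom-mounted blade
shorter than the settled bed (2.5 cm vs ~6.5 cm), mixing is two-zone — the
swept layer homogenizes quickly while the upper bed mixes slowly through
induced flow. At desk scale some seeds show a mid-run regime change
(decay, then plateau) that no time-series model can anticipate from the
first half of the record; the half-split validation error is honest about
this (see the test suite and the acceptance report).

## Segregation index

With particles labelled 1 or 2, `C_ij` counts contacts between labels i and
j. A contact is geometric proximity: centre distance at most
`(r_i + r_j)(1 + tolerance)` with a default tolerance of `1e-3`, a definition
deliberately decoupled from the force-model overlap so that rounded snapshot
files census identically. Unordered pairs are credited to both orderings, so
`C_12 = C_21` identically. The index

```
psi = C11 / (C11 + C12) + C22 / (C22 + C21)
```

is 2 for a fully unmixed bed, 1 in expectation under uniform random mixing,
and 0 for a perfectly alternating arrangement. It is label-swap symmetric and
confined to [0, 2]. When a label has no contacts in a domain, psi is
undefined and reported as missing, never interpolated. Radial structure is
captured by partitioning contacts into equal-width annuli (default three,
R1 at the axis) by the contact midpoint; merging the per-region censuses
reproduces the bulk census exactly.

## ARIMA endpoint forecasting

psi(t) is fitted with ARIMA(p, d, q) by maximum likelihood
(`stats::arima(method = "ML")`), searching p in 0..100, d and q in 0..2, and
selecting by AIC (`2k - 2 logLik`, k counting all estimated parameters plus
the innovation variance). The default search expands p stepwise for each
(d, q) and stops after 10 consecutive non-improvements; `exhaustive = TRUE`
restores the full grid. AIC ties go to the lower `p + q`, then the lower `p`.

Five numerical choices emerged from implementation experiments and are part
of the engine's contract:

* **Drift as a candidate.** `stats::arima` has no drift term for d = 1, but a
  persistently decaying psi has non-zero mean differences, and a drift-free
  model flattens every long-horizon forecast. For d = 1 the search therefore
  fits each order both with and without a linear drift regressor and lets
  the criterion decide.
* **Boundary-root admissibility.** Fits whose AR or MA polynomial has a root
  within 0.001 of the unit circle are excluded from selection: they are
  spurious common-factor or overdifferenced artifacts (the canonical example
  is an ARMA(1,1) on white noise with `ar ~ 0.85, ma ~ -1.0`) whose forecasts
  are untrustworthy. This is the same guard `auto.arima` applies.
* **Conditional fallback.** Exact ML is ill-posed on strongly trended,
  low-noise series: the stationary initial-state density forces AR roots
  onto the unit circle even when the process has an interior AR
  representation (a mixing curve relaxing toward psi = 1 is the archetype).
  When the exact fit fails or is boundary-inadmissible, the order is refitted
  by conditional sum of squares, which has no initialization penalty and
  recovers the interior coefficients. Forecasts of conditionally estimated
  fits continue the conditional recursion itself (with future innovations at
  zero and psi-weight standard errors); the exact Kalman forecast is
  inconsistent with conditional estimates on such series because the filter
  attributes the initial transient to enormous innovations.
* **A common selection basis, and d by validation.** Exact likelihoods are
  not comparable across `d` (differenced fits cover `n - d` observations,
  and when the innovation variance is small every extra observation
  contributes positive log-density), nor between exact and conditional
  estimation. Within each differencing depth, orders are therefore compared
  by `2k` minus twice a Gaussian pseudo-log-likelihood of one-step
  prediction residuals over a common post-burn-in window (each fit's
  reported `aic` remains the exact `2k - 2 logLik` of its estimator). The
  differencing depth itself is chosen by rolling-origin validation — each
  depth's winner is refitted on the first two thirds of the window and
  scored on its multi-step forecast of the final third — because no
  in-sample criterion measures extrapolation across `d`; a higher depth
  displaces a lower one only when its validation error is materially (>10%)
  smaller, so stationary series are not differenced on validation noise.
* **Deterministic inputs.** When a conditional fit is exact (residual
  variance below `1e-10` of the differenced-series variance) the input is a
  noiseless AR recursion: the fit is marked degenerate with `AIC = -Inf`, so
  the parsimony tie-break selects the smallest exact order and the forecast
  is exact. A constant series (zero variance after differencing)
  short-circuits the same way with a closed-form continuation.

One property that plain AIC minimization does *not* deliver deserves naming:
on pure white noise the strict winner is the null (0, 0, 0) model only about
40% of the time — with ~50 candidate orders, small spurious AIC gains are
expected by construction. What does hold, and what the tests assert, is that
no differencing is selected and the winner's AIC gain over the null stays
below any material size.

Validation follows the half-split protocol: select and fit on the first half
of the record, forecast the second half, and report the mean absolute
percentage error (the maximum APE is reported alongside; the error metric had
to be chosen, and MAPE is the conventional reading of an "error margin").
The endpoint `T_end` is the first time the forecast path reaches the cutoff
(default psi = 1.1, chosen because the asymptotic approach of psi to 1 makes
"psi = 1" an erroneously long target), linearly interpolated between forecast
steps. If the observed series already crosses, the observed crossing is
returned and flagged; if the forecast never crosses within the horizon cap
(default 100x the training length), an explicit no-crossing result is
returned rather than a fabricated time. The crossings of the 95%
prediction-interval bounds give an `[t_early, t_late]` interval.

## Surrogate models

The feature table has one row per run: the nine descriptors in SI units plus
the response `t_end_s` and a provenance tag; rows without a resolved crossing
are excluded with a logged count. Four regressor families are evaluated:
random forest, RBF support-vector regression, partial least squares, and the
elastic net. Evaluation is leave-one-out cross-validation with tuning inside
each training fold: the forest by its own out-of-bag error over
features-per-split {2, 3, 5, 9} and depth {3, 5, 10, unlimited} (500 trees);
SVR by an inner 5-fold CV over `C` in {0.1, 1, 10, 100} and gamma in
{1/9, 0.01, 0.1}; PLSR over 1-5 components; the elastic net by `cv.glmnet`
over mixing {0.1, 0.5, 0.9}. Descriptors are standardized with training-fold
statistics for SVR/PLSR/elastic net and left raw for the forest (whose
predictions are invariant under monotone rescaling). R^2 is `1 - SSE/SST` on
the pooled out-of-fold predictions and may be negative; `t_end` is used
untransformed by default with an optional log flag left to the caller.

Permutation importance is computed strictly out-of-fold: the forest is grown
with `keep.inbag = TRUE`, and each row is scored only by the trees whose
bootstrap excluded it. A descriptor's importance is the percentage increase
in this out-of-bag MSE after permuting its column, averaged over replicates
(default 20); a zero-variance column has importance 0 by definition. Rankings
are by decreasing importance; values are not normalized, preserving the
percent-MSE scale.

## Synthetic generators: what they emulate and what they do not

The parametric mixing curve is
`psi(t) = 1 + (psi0 - 1) exp(-rate_k * rpm t / 60) + noise`, clipped to
[0, 2], with the analytic cutoff-crossing time attached. The
exponential-in-revolutions form is a fixture choice that reproduces two
qualitative facts of the DEM output — decay toward psi = 1 driven by
revolution count, and slower wall-clock mixing at lower RPM — but not its
harder features: blade-passage periodicity, census noise that grows as
contacts rarefy, or the two-zone regime changes described above. Passing the
synthetic forecasting tests therefore demonstrates correctness of the
machinery, not that real mixing curves are this easy.

The design-table generator Latin-hypercube samples the nine descriptors over
desk-scale ranges (particle radius 1.5-4.5 mm, density 800-1500 kg/m^3,
restitution 0.4-0.9, cohesion 0-1e5 J/m^3, friction 0.05-0.5, modulus
5e6-5e7 N/m^2, 500-5000 particles, 10-60 RPM, fill 2-10 cm) and plants a
documented response: `ranking` (additive effects with importance order
fill level > RPM > particle radius and six inert descriptors, mirroring the
qualitative finding that fill level dominates mixing time), `interaction`
(a fill x RPM product term that a linear model cannot represent), `linear`,
or `noise`. The `interaction` surface is a two-zone threshold — deep cakes
stirred slowly take a step jump in mixing time, mirroring the bottom-blade
regime change seen in the DEM runs — chosen because an axis-aligned
non-additive surface is representable by tree ensembles at this sample size
while remaining invisible to a linear model (smooth product terms at n = 40
among six inert descriptors are learnable by neither). Recovery tests assert
the planted structure, with thresholds fixed before the replicates were run.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed and restores the caller's RNG
state; the pipeline manifest records seeds, package versions and an md5 hash
of every output file, and reruns with an identical configuration reproduce
identical hashes. The test-suite problem sizes are deliberately desk-scale:
settled beds of 400-1200 particles for metric tests, one reference DEM run
of 2000 particles x 3 s for the half-split check, 25-50 replicates for the
order-recovery Monte-Carlos and 20 for the surrogate recovery suites —
chosen so the whole suite completes in well under half an hour on one CPU
while keeping the Monte-Carlo assertions statistically meaningful.

## Known limitations

* The contact model reconstructs a standard Hertz-Mindlin + SJKR family; the
  exact production-code variant (dashpot form, tangential history details)
  may differ in detail.
* Blade geometry is a minimal abstraction (flat vertical plates through the
  axis); real AFD impellers are pitched and curved, which changes axial
  turnover and hence absolute mixing times.
* Half-split forecast accuracy is regime-dependent: a mixing-rate change
  after the training window (observed at desk scale with a bottom blade and
  a deep bed) is unforecastable in principle from the first half alone.
* LOOCV R^2 on small tables is noisy; method rankings are asserted only as
  seeded Monte-Carlo frequencies, not as single-run facts.
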