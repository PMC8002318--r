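---
title: "Semi-mechanistic residence-time moments in twin-screw wet granulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-mechanistic residence-time moments in twin-screw wet granulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsgrtd)
```

## The problem

Continuous wet granulation in a co-rotating twin-screw granulator (TSG)
turns a powder stream and a pumped binder liquid into granules. How long
material spends in the barrel — summarized by the residence time
distribution (RTD) — governs mixing, traceability and control. `tsgrtd`
predicts the two central moments of the RTD, the mean residence time (MRT,
seconds) and the normalized variance $\sigma^2/\tau^2$, from quantities a
process engineer already knows: screw geometry, screw configuration, feed
rates and densities. It does so with reduced-order *surrogate factors*
rather than a full flow simulation, which keeps the model transferable
across equipment scales at the cost of a handful of tuned constants.

## The model

Three volumetric building blocks are computed from geometry and operating
conditions:

* **Net volumetric feed rate** $FR_v$ (m³/s): powder volume flow plus
  liquid volume flow, where the liquid mass rate is the powder mass rate
  times the liquid-to-solid (LS) ratio,
  $FR_v = \dot m_p/\rho_p + \dot m_p \cdot LS/\rho_l$.
* **Available volume** $V$ (m³): the stagger-angle sector volume of the
  kneading blocks, $4\cdot\tfrac12 R^2\, NK\, t\, SA_{deg}\,\pi/180$, plus
  the conveying sections approximated as a stack of many thin
  pseudo-kneading discs (below).
* **Displacement rate** $D$ (m³/s): revolutions per second times the
  available volume of one final lead of conveying screw.

These feed three surrogate factors with tuning exponents $b_2,b_3,b_4,b_6$
and scales $b_1,b_5$:

$$\mathrm{Holdup} = FR_v^{\,b_2}\, V, \qquad
  \mathrm{Flow} = FR_v^{\,b_3} D^{\,b_4}, \qquad
  \mathrm{Mixing} = \frac{SA_{deg}\, D^{\,b_6}\, KB\, \pi}{NK_{pb}\, 180},$$

where $KB$ is the number of kneading blocks and $NK_{pb}$ the elements per
block. The predictions are

$$\mathrm{MRT} = b_1 \frac{\mathrm{Holdup}}{\mathrm{Flow}}, \qquad
  Pe = b_5 \frac{\mathrm{Flow}}{\mathrm{Mixing}}, \qquad
  \sigma^2_{norm} = \frac{2}{Pe} + \frac{8}{(Pe+2)^2},$$

subject to two dimensional-consistency constraints:
$-b_2+b_3+b_4 = 1$ (MRT in seconds) and $b_3+b_4 = b_6$ ($Pe$
dimensionless). When they hold, both predictions are invariant to a common
rescaling of all volumetric quantities — a property the test suite asserts
at scale factors $10^3$ and $10^9$.

The variance relation is the open-open dispersion-boundary form: in powder
handling, segregation lets dispersion extend beyond both vessel boundaries,
unlike the closed-closed assumption familiar from reactor textbooks. The
form above, with $8/(Pe+2)^2$, is the package default; the classical
open-open relation $2/Pe + 8/Pe^2$ differs from it at small $Pe$ and is
available behind `form = "open_open"` in `variance_from_peclet()` for
comparison. The difference is surfaced, not silently reconciled. Variance
is modeled on the normalized (dimensionless) scale; a dimensional variance
is just $\sigma^2_{norm}\cdot \mathrm{MRT}^2$.

Two further readings deserve note. First, the liquid term of the feed rate
uses liquid mass rate = powder mass rate × LS ratio — the only reading
under which an LS *ratio* is meaningful. Second, the mixing factor divides
by the elements per block, and the Peclet model is treated as the exact
quotient of the flow and mixing factors, so the same count appears there;
`denominator = "total"` in `predict_peclet()` divides by the total element
count instead for users who prefer that variant.

## The conveying-screw discretization

A conveying screw is a continuous helix, so its "stagger-angle sector
volume" is not directly defined. The package approximates a conveying
section of length $L$ and lead $\ell$ as $n = \mathrm{round}(L/\delta)$
discs of thickness $L/n$, with the section's total twist
$\Theta = 360\,L/\ell$ degrees spread over the $n-1$ gaps between discs
(21 unit discs at 18° between neighbours reproduce one full turn over 21
length units: 20 gaps × 18° = 360°).

This discretized volume does **not** converge as the disc thickness
$\delta \to 0$: the product $n \cdot t \cdot SA \propto L\,\Theta/n$
vanishes. The step $\delta$ is therefore an explicit model configuration
(`fe_disc_m`, default 1 mm — one unit-thickness disc), not a numerical
tolerance. Its choice rescales the conveying volume and the displacement
rate by a common factor, which the fitted scale constants $b_1$ and $b_5$
absorb; what matters is holding it fixed across a dataset. The leading
factor 4 in the sector-volume formula is likewise implemented literally as
part of the model definition.

## Identifiability: what the data can and cannot pin down

With $b_4 = 1 + b_2 - b_3$ eliminated (the package enforces the seconds
constraint exactly by construction, not through a solver tolerance), the
MRT prediction can be rewritten as

$$\mathrm{MRT} = b_1\, FR_v^{\,d}\, V\, D^{-(1+d)}, \qquad d = b_2 - b_3 .$$

MRT data therefore determine only $b_1$ and the *difference* $d$; the pair
$(b_2, b_3)$ is a one-dimensional ridge, and any reported $(b_2,b_3)$ is
one point on it. The variance model breaks the tie: with $b_6 = b_3 + b_4$
exact, $Pe \propto b_5\,(FR_v/D)^{\,b_3}$, so variance observations
identify $b_3$ (and hence $b_2 = b_3 + d$) individually.
`fit_variance(refit_shape = TRUE)` exploits exactly this: it optimizes
$(b_5, b_3)$ while holding $d$ and $b_4$ at their MRT-fit values, leaving
the MRT predictions untouched and both constraints exact. The package's
recovery tests assert near-exact recovery of $(b_1, d, b_4)$ from the MRT
fit alone and of all six constants after the variance fit.

## The fitting algorithm

`fit_mrt()` minimizes the RMSE between observed and predicted MRT (the
optimizer works on the mean squared error with an analytic gradient — the
same argmin, but smooth at a perfect fit) over $(\log b_1, b_2, b_3)$ with
bounded quasi-Newton descent (PORT routines) inside box bounds, default
$[10^{-3}, 10]$ for every constant. The procedure:

1. a seeded train/test split (default 75% train), stratified by
   `dataset_tag` so pooled datasets keep their proportions in every
   partition;
2. `n_multistarts` (default 8) seeded starting points, $b_1$ drawn
   log-uniformly across its bounds and the exponents uniformly in
   $[0.1, 2.5]$ (the search bounds stay wider);
3. for each start, a k-fold chain (default $k = 5$): the optimum on one
   fold's training complement warm-starts the next fold, each held-out
   fold records a validation RMSE, and the chain ends with a descent on
   the full training set;
4. the chain with the least mean validation RMSE supplies the reported
   parameters; fold RMSEs, the seed, and an objective trace (start/end
   value of every accepted descent) are kept in the result.

Restarting "when the end-point criteria are not met" is realized as a
fresh seeded multistart draw. Every random step flows from one integer
seed, so identical inputs reproduce the result byte for byte — the
serialized parameter JSON of two runs with the same seed compares equal as
files, and the suite asserts it.

Sequential fitting (MRT first, then variance) is the default, consistent
with the published parameter tables where $b_6$ equals $b_3+b_4$ at
printed rounding; the joint shape refit is the documented option above.
Rows with missing variance are dropped from the variance objective only.

## The synthetic-data generator

There is no bundled experimental data; the generator produces designed
experiments with a known ground truth so the whole pipeline is testable
offline. Three presets mirror the collated literature datasets in factor
ranges and run counts: a 66-run and a 51-run study on a 25 mm-class
pilot granulator (feed rate 10–25 kg/h, screw speed 500–900 RPM, 2–12
kneading elements; stagger angle 30–90° with LS fixed at 11.5% in the
first, 30–60° with LS 6–8% in the second) and a 24-run study on a
lab-scale extruder (0.5–2 kg/h, 200–500 RPM, LS 70–100% for a
microcrystalline-cellulose-type material). Factor values are sampled
random-uniformly within those ranges; kneading counts snap to even values
factored as blocks of two. Gridded (full-factorial) designs are available
for main-effects work. The equipment dimensions behind the presets
(12.5 mm screw radius, element thickness half the radius, lead equal to
the diameter for the pilot class; a 6 mm-radius lab machine; lactose-like
600 kg/m³ and microcrystalline-cellulose-like 320 kg/m³ bulk densities)
are stated defaults chosen once as physically plausible values — the
source studies' true dimensions are not public in this form — and every
value is overridable.

Observation noise is multiplicative lognormal with unit mean:
$y_{obs} = y_{model}\exp(\varepsilon)$,
$\varepsilon \sim N(-s^2/2,\, s^2)$, $s^2=\log(1+cv^2)$. Residence times
are positive with errors that scale with magnitude, which makes a
relative-error model the natural choice; a 5% coefficient of variation is
used as the default measurement-noise level in the recovery tests. A
Monte-Carlo test confirms the unit-mean correction. An option drops a
fraction of 90°-stagger runs, emulating the data loss that occurs when
high-stagger configurations jam.

What passing the synthetic tests does *not* show: real tracer data carry
structured error (detector calibration, baseline drift, granule-size
feedback on holdup) that no independent lognormal factor reproduces, and
real designs confound factors that random sampling keeps independent.
Recovery results here certify the algorithm, not the model's fidelity to
any particular machine.

## Numerical choices and degenerate inputs

* Constraints are enforced by variable elimination, never by a penalty in
  the production path (a penalty-based fit is kept as a test oracle and
  agrees with elimination on synthetic data); residuals of externally
  supplied, two-decimal parameter sets are accepted at tolerance 0.015,
  internal ones at $10^{-9}$.
* A derived $b_4$ outside the box bounds is discouraged by a quadratic
  penalty inside the objective; the optimum never sits there in practice.
* `nlminb` terminations are treated as converged unless an
  iteration/evaluation limit was hit — on the $(b_2,b_3)$ ridge the
  gradient test can report "false convergence" at a perfectly good
  optimum.
* Pure-conveying screws (no kneading section) are valid for MRT but raise
  an explicit error in the Peclet/variance path, and variance fitting on
  tables without usable variance rows returns an explicit "not fitted"
  result.
* Band membership in parity reports uses closed intervals (a prediction
  exactly at the band edge is in-band). Default bands: ±1 s for MRT,
  ±0.1 for normalized variance; long-residence-time equipment warrants
  ±20 s.
* Ties between multistart chains resolve to the first-drawn chain, which
  keeps results seed-deterministic.

## Problem sizes

The bundled tests fit 20–60-run synthetic tables with 4–8 multistarts and
4–5 folds; each full fit takes well under a second, and the whole suite a
few seconds. These sizes were chosen to match the collated studies' scale
(24–66 runs per dataset, 141 pooled) while keeping the examples quick to
reproduce.

## Worked example

```{r example, eval = FALSE}
truth <- {
  b2 <- 0.99; b3 <- 0.65; b4 <- 1 + b2 - b3
  model_parameters(0.33, b2, b3, b4, 5.35, b3 + b4)
}
tab <- simulate_observations(
  generate_doe(preset_dataset("kumar2015-like", n_runs = 60, seed = 11)),
  truth, noise_spec(mrt_cv = 0.05, var_cv = 0.05, seed = 12))

pipe <- crossval_pipeline(tab, refit_shape = TRUE, seed = 11)
pipe$mrt_fit$params     # b1 and b2 - b3 near the truth; b4 = 1 + b2 - b3
pipe$evaluation         # held-out RMSE on the seconds scale, parity bands
```

## Known limitations

* Only the central moments are modeled; no full RTD curve $E(t)$ is
  predicted or fitted.
* The conveying discretization is a modeling convention, not a convergent
  numerical scheme; comparisons across studies require a shared
  `fe_disc_m`.
* The surrogate exponents have no guaranteed mechanistic interpretation
  off the collated datasets' factor ranges; extrapolation (for example to
  very high LS ratios) rests on the reciprocal $b_1$–LS trend, which is an
  empirical observation with four points behind it.
* Screw clearances, flight-width and intermesh corrections, granule-size
  feedback on holdup, and population-balance coupling are out of scope.
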