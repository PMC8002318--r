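# tsgrtd

Semi-mechanistic prediction of residence-time distribution (RTD) central
moments — the mean residence time (MRT) and the normalized variance — in
twin-screw wet granulation.

Twin-screw granulators (TSGs) make pharmaceutical granules continuously:
powder and binder liquid enter at one end, granules leave at the other.
How long material spends inside, and how much it axially disperses on the
way, controls mixing quality, traceability and process design. Measuring a
full RTD needs tracer experiments; `tsgrtd` instead predicts the two
moments that matter most from quantities an engineer already has — screw
geometry, screw configuration (kneading elements, blocks, stagger angle),
feed rate, screw speed, liquid-to-solid ratio and densities — via
reduced-order *holdup*, *flow* and *mixing* factors. The package is aimed
at process modelers and engineers who want a transferable, fittable moment
model and a fully reproducible fitting pipeline, without CFD or DEM.

## The model in brief

Three volumetric quantities are computed per run: the net volumetric feed
rate `FRv` (powder + liquid volume flow, m³/s), the available screw volume
`V` (stagger-angle sector volume of the kneading blocks plus a
finite-disc approximation of the conveying sections, m³), and the
displacement rate `D` of one lead of conveying screw (m³/s). With tuning
constants `b1..b6`:

    Holdup = FRv^b2 * V          Flow = FRv^b3 * D^b4
    Mixing = SA * D^b6 * KB * pi / (NKpb * 180)

    MRT     = b1 * Holdup / Flow            subject to  -b2 + b3 + b4 = 1
    Pe      = b5 * Flow  / Mixing           subject to   b3 + b4 = b6
    Var     = 2/Pe + 8/(Pe + 2)^2           (open-open dispersion boundary)

The two exponent constraints make MRT come out in seconds and the Peclet
number dimensionless; the package enforces them *exactly* by variable
elimination inside the fit. Fitting is seeded, k-fold cross-validated,
multistart bounded quasi-Newton on the RMSE; a synthetic
design-of-experiments generator with known ground truth makes the whole
pipeline testable offline. See the methods vignette
(`vignettes/tsgrtd-methods.Rmd`) for assumptions, identifiability and
numerical choices.

## Worked example

Simulate a 60-run synthetic study in the factor ranges of a published
66-run pilot-scale dataset (feed rate 10–25 kg/h, 500–900 RPM, 2–12
kneading elements, stagger 30–90°, LS 11.5%), using that dataset's
published constants as ground truth with 5% multiplicative measurement
noise, then refit from scratch:

```r
library(tsgrtd)

b2 <- 0.99; b3 <- 0.65; b4 <- 1 + b2 - b3
truth <- model_parameters(0.33, b2, b3, b4, 5.35, b3 + b4)

tab <- simulate_observations(
  generate_doe(preset_dataset("kumar2015-like", n_runs = 60, seed = 11)),
  truth, noise_spec(mrt_cv = 0.05, var_cv = 0.05, seed = 12))

pipe <- crossval_pipeline(tab, refit_shape = TRUE, seed = 11)
pipe
#> RTD pipeline (seed 11): 45 train / 15 test runs
#> RTD model fit (mrt_s)
#> Model parameters: b1 = 0.3263929 b2 = 1.489014 b3 = 1.157879 b4 = 1.331135
#>   training RMSE: 0.017921
#>   fold validation RMSE: 0.01407, 0.01931, 0.02518, 0.02209, 0.01616
#>   seed: 11 | multistarts: 8 | converged: TRUE
#> RTD model fit (varnorm)
#> Model parameters: b1 = 0.3263929 b2 = 0.9666645 b3 = 0.6355298 b4 = 1.331135 b5 = 5.285197 b6 = 1.966664
#>   training RMSE: 0.107901
#>   seed: 11 | multistarts: 5 | converged: TRUE
#> RTD evaluation:
#>   MRT RMSE: 0.0107446 s | in band: 1
#>   varnorm RMSE: 0.0887902 | in band: 0.8667
```

Reading this: the MRT fit recovers the scale `b1` (0.326 vs 0.33) and the
derived exponent `b4` (1.331 vs 1.34) from noisy data; `b2` and `b3` look
off individually because MRT data only pin their *difference* (1.489 −
1.158 = 0.331 vs the true 0.34) — the variance refit then identifies them
individually (0.967/0.636 vs 0.99/0.65) along with `b5` (5.285 vs 5.35).
Held-out test RMSE is 0.011 s with every MRT prediction inside the ±1 s
parity band, and the variance RMSE of 0.089 sits at the 5% noise floor.
Note `-b2 + b3 + b4` equals 1 to machine precision in both fits.

The published scale constants also rise with each dataset's average
liquid content, linearly on reciprocal axes:

```r
fx <- published_fixtures()$parameters
reciprocal_b1_trend(fx$b1, fx$ls_avg_pct)
#> Reciprocal trend 1/b1 = 0.34452 + 18.204 * (1/LS);  R^2 = 0.99401
```

A thin command-line front end over the same functions lives at
`inst/scripts/tsgrtd.R` (subcommands `simulate`, `fit`, `crossval`,
`predict`, `evaluate`, `report`).

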