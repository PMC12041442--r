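# flushcurve

Repeated Gompertz growth-curve analysis for crops that yield in
successive flushes.

Perennial crops such as greenhouse cut roses are harvested in waves:
each *flush* of synchronized flowering rises, peaks and exhausts itself
before the next begins. Treatment effects (e.g. compost amendments in a
randomized complete block design) are therefore better expressed per
flush than per calendar month. `flushcurve` implements the full chain:

- **Synthetic data** — a generator for randomized block multi-flush
  experiments with known ground truth: per-bed Gompertz curves with
  block/bed random effects, integer daily counts via carry-forward
  rounding, and optional harvest-pause artifacts that conserve totals.
- **Flush segmentation** — smooth the pooled cumulative series
  (penalized spline or LOESS), difference, roll (7-day centered mean),
  and place boundaries at interior rate minima; merge and refine
  candidates; quantify smoothing-parameter sensitivity.
- **Gompertz mixed model** — per flush,
  `y' = A_i exp(-exp(B_i - C t')) + e` with treatment fixed effects and
  block/bed random effects on `A` and `B`, a shared `C`, observation
  weights, estimated by a hand-rolled SAEM with Louis-information
  standard errors; deterministic two-stage fallback.
- **Additive benchmark** — a penalized-spline mixed model
  (`mgcv`) per flush, AIC-based basis-dimension selection, and
  pointwise model comparison on Efron's R².
- **Reporting** — parameter trajectories across flushes, Wald
  treatment contrasts using the joint fixed-effect covariance, CSV/JSON
  reports, diagnostic figures, and a YAML-driven command line interface.

## Worked example

Simulate the default 18-month, 8-flush experiment (5 treatments x 3
blocks, with a 13-day harvest pause mid-series), segment it and fit both
model families:

```r
library(flushcurve)
report <- run_pipeline(pipeline_config(pause = pause_spec(), seed = 42))
report
#> Repeated growth-curve run report
#>   flushes detected: 8  Gompertz fits: 8  additive fits: 8  failures: 0
#>   Efron R^2 (Gompertz): 1, 0.999, 0.84, 1, 1, 1, 1, 1
```

The pause falls in flush 3, which is why its unweighted R² dips; all
other flushes fit essentially perfectly. Detected boundaries (true
flush starts: 91, 129, 186, 240, 302, 363, 426, 490 — the default GAM
smoother places late boundaries a few days early; see the vignette):

```r
report$boundaries
#> Flush boundaries (8 flushes): 91, 126, 183, 236, 296, 356, 417, 480
```

The asymptote trajectory of the control shows the maturation of the
crop (true values 800, 1000, 1200, 2400, 2800, 3000, 3000, 2600):

```r
subset(trajectory_table(report), parameter == "A" & treatment == "Control")
#>  flush treatment parameter estimate       se
#>      1   Control         A  741.644 57.06429
#>      2   Control         A 1053.461 55.63090
#>      3   Control         A 1171.506 40.71519
#>      4   Control         A 2415.512 44.78301
#>      5   Control         A 2922.054 60.66406
#>      6   Control         A 3048.405 66.88598
#>      7   Control         A 3125.624 46.99849
#>      8   Control         A 2618.171 40.38767
```

Treatment contrasts against the control use the joint covariance of the
fixed effects (truth for flush 4: R +500, T +400, C +300, R50 +450):

```r
subset(report$contrasts, flush == 4 & parameter == "A")
#>  flush treatment parameter difference    se lower upper significant
#>      4         C         A      329.4 63.35 205.2 453.6        TRUE
#>      4         R         A      555.2 63.37 431.0 679.4        TRUE
#>      4       R50         A      505.0 63.39 380.7 629.2        TRUE
#>      4         T         A      375.8 63.34 251.6 499.9        TRUE
```

Individual fits carry everything downstream analyses need:

```r
report$gompertz_fits[[4]]
#> Gompertz mixed-model fit (saem)
#>   observations: 900  Efron R^2: 0.9998
#>  parameter treatment  estimate        se
#>          A         C 2744.9267 4.482e+01
#>          A   Control 2415.5117 4.478e+01
#>          A         R 2970.7381 4.485e+01
#>          A       R50 2920.4688 4.485e+01
#>          A         T 2791.2931 4.478e+01
#>          B         C    2.7764 4.733e-02
#>          B   Control    2.5822 4.732e-02
#>          B         R    2.8019 4.755e-02
#>          B       R50    2.7727 4.728e-02
#>          B         T    2.8136 4.744e-02
#>          C      <NA>    0.1087 1.091e-04
```

Real data enter through `read_yield_csv()` (long format: `bed_id`,
`block_id`, `treatment`, `day`, `stems`) and
`pipeline_config(input = "yield.csv")`.

## Command line

A thin CLI wraps the same functions (see the header of
`inst/cli/flushcurve.R` for the YAML schema):

```sh
Rscript inst/cli/flushcurve.R simulate --config cfg.yml --out out/
Rscript inst/cli/flushcurve.R segment  --config cfg.yml --out out/
Rscript inst/cli/flushcurve.R run      --config cfg.yml --out out/
```

## Reproduction

The test suite (testthat, 3rd edition) contains unit, property and
acceptance tests; the acceptance file asserts, among others: the
Gompertz inflection identity over 1000 random parameter sets, exact
hand-checks of Efron's R², boundary recovery within 3 days on noiseless
8-flush data over 20 seeds, SAEM-vs-NLS oracle agreement within 1%
without random effects, parameter recovery and ≥90% Wald-interval
coverage on the default design over 20 seeds, exact weight neutrality,
and an exact flush-partition round-trip.

```sh
R CMD INSTALL --no-docs .
Rscript -e 'testthat::test_dir("tests/testthat", package = "flushcurve",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`scripts/acceptance.R` runs the full synthetic pipeline against the
installed package and writes the headline quantities (detected
boundaries, per-flush asymptotes, contrasts, recovery errors, R² per
model family) as JSON.
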