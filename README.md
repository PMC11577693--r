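# prosim

Monte Carlo simulation of treatment-effect estimators for bounded, discrete
patient-reported-outcome (PRO) scores in balanced two-arm randomised
controlled trials.

## The problem

PRO scores such as the SF-36 dimension scores are bounded (0–100), discrete
(a dimension may take only 4, 10 or 26 distinct values) and often piled up
at the scale ends, yet the construct they measure is plausibly a latent
continuous quantity. Trial statisticians therefore face a modelling choice:

* **MLR** — ordinary least squares of the observed score on the treatment
  indicator; estimates the difference in arm means of the *observed* score.
* **Tobit** — censored-Normal maximum likelihood with censoring at 0 and
  100; estimates the difference in arm means on the *latent* scale,
  `Y* = β₀ + β₁·arm + ε`, `ε ~ N(0, σ²)`, with `Y = max(0, min(100, Y*))`
  observed. Boundary scores contribute `Φ` tail terms to the likelihood.
* **Median (LAD) regression** — minimises `Σ|y − β₀ − β₁·arm|`; estimates
  the difference in arm medians, with sparsity-based (kernel density at
  zero residual, Hall–Sheather bandwidth) standard errors.

`prosim` generates trials from a latent `Normal(μ = 50, σ = 22)` score with
a location-shift treatment effect `x ∈ {0, 4.4, 11, 17.6, 22}` (Cohen's
d of 0–1.0), clamps draws to [0, 100], discretises them onto a 4-, 10- or
26-level score grid, fits the three estimators to every simulated trial,
and summarises each scenario with the standard simulation performance
measures — bias, empirical SE, MSE, coverage of the 95% CI, Type I error /
power — together with their Monte Carlo standard errors. The full factorial
design is 5 effects × 3 grids × 6 sample sizes (100–1600) = 90 scenarios at
5000 repetitions each.

A common-random-numbers scheme keys the latent draws by
`(root seed, n, repetition)` only, so every grid and every effect size
reuses the identical base Normal sample; results are bit-for-bit
reproducible and independent of execution order.

## Worked example

A reduced design (two effects, two grids, two sample sizes, 200
repetitions) runs in a few seconds:

```r
library(prosim)
cfg <- study_config(root_seed = 42, dgm_effects = c(0, 22),
                    grids = c("RE4", "MH26"),
                    sample_sizes = c(100, 400), nsim = 200)
res <- run_study(cfg, verbose = FALSE)
make_table5(res$performance)
#>     n dgm effect_x MLR_RE4 TOBIT_RE4 MEDIAN_RE4 MLR_MH26 TOBIT_MH26 MEDIAN_MH26
#> 1 100   1        0  -0.270    -0.256     -2.464   -0.072     -0.057       -0.42
#> 2 400   1        0   0.232     0.264      0.749    0.171      0.174        0.07
#> 3 100   2       22  21.086    25.963     15.448   20.904     22.137       21.66
#> 4 400   2       22  21.439    26.435     15.568   21.096     22.383       22.00
```

Rows are (sample size × data-generating mechanism), columns are mean
treatment-effect estimates per (method × grid). The pattern of the full
study is already visible: under the null (DGM 1) all methods centre near 0;
at a 22-point latent effect MLR underestimates slightly on the coarse
4-level grid (≈ 21.4, discretisation attenuates the shift), Tobit
*overestimates* markedly there (≈ 26.4), and median regression collapses
onto multiples of the 33.3-point score gap (mean ≈ 15.6). On the
near-continuous 26-level grid all three land close to 22.

```r
subset(res$performance, scenario_id == "x22_RE4_n400")[,
  c("method", "bias", "emp_se", "coverage", "rejection_rate")]
#>  method   bias emp_se coverage rejection_rate
#>     MLR -0.561   2.20    0.970           1.00
#>   TOBIT  4.435   2.89    0.710           1.00
#>  MEDIAN -6.432  16.28    0.045           0.49
```

Bias is measured against the predefined latent effect (22); Tobit's +4.4
bias and 0.71 coverage on the 4-level grid, and the huge empirical SE and
near-zero coverage of median regression, reproduce the study's qualitative
findings at small cost.

Per-repetition estimates (`res$estimates`) feed the diagnostic plots:
`plot_estimates_hist()`, `plot_est_vs_se()`, `plot_method_vs_method()` and
`plot_performance(res$performance, "coverage")`.

The full design is `study_config(root_seed = <seed>)` followed by
`run_study()`; expect roughly 30–60 minutes on one CPU. A thin command-line
wrapper is installed at `inst/scripts/prosim.R`
(`Rscript prosim.R run --config study.yaml --out DIR`, `summarise DIR`,
`plot DIR --kind line --measure coverage`).

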