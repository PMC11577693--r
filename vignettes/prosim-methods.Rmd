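---
title: "Simulation design and estimator details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation design and estimator details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosim)
```

## What the simulation emulates

`prosim` studies a single question: when a randomised trial's outcome is a
bounded, discrete PRO score that plausibly measures a latent continuous
construct, how do the three standard "difference in location" estimators —
ordinary least squares (MLR), censored-Normal maximum likelihood (Tobit),
and median/LAD regression — behave?

The data-generating mechanism is deliberately simple and favourable to the
latent-variable view:

1. **Latent scores.** Each subject's latent score is drawn from
   `Normal(μ = 50, σ = 22)` (score points). These defaults describe a
   typical SF-36 bodily-pain arm mean and SD observed in practice.
2. **Treatment effect.** A pure location shift `x` is added to every
   treatment-arm draw. The default grid of shifts — 0, 4.4, 11, 17.6 and 22
   points — corresponds to Cohen's d of 0, 0.2, 0.5, 0.8 and 1.0 at
   σ = 22, spanning "no effect" to "very large effect".
3. **Clamping.** Draws outside [0, 100] are set to the boundary. (With the
   default μ and σ roughly 1.2% of control draws fall below 0 and 1.2%
   above 100.)
4. **Discretisation.** The clamped value is mapped onto a discrete score
   grid by left-open/right-closed bins: a value in `(edge[j-1], edge[j]]`
   takes the j-th printed score, and a value exactly on an edge takes the
   *lower* score. The three built-in grids are the published 4-, 10- and
   26-level SF-36 dimension scales (`RE4`, `BP10`, `MH26`), including their
   non-midpoint score values (e.g. 55.6 and 66.7 on the 10-level scale);
   `make_grid(k)` for any other `k` builds an equally spaced grid with
   midpoint edges. Clamping before discretisation is mathematically
   redundant (the outer bins extend to ±∞) but is kept so clamped values
   are reportable per subject.

Arms are always balanced (`n/2` per arm) and no covariates are generated:
the estimators fit an intercept and the arm indicator only.

What the generator does **not** emulate: item-level questionnaire
responses, skewed or heteroscedastic latent distributions, unbalanced
arms, missing data, clustering or repeated measures. Passing tests
therefore demonstrate estimator behaviour under an idealised latent-Normal
location-shift world — the setting in which MLR and Tobit are given their
best chance — not robustness to the many ways real PRO data deviate
from it.

## Randomness and reproducibility

Every random draw in a study descends from one integer `root_seed`. The
latent base sample of repetition `r` at total size `n` is drawn from a
substream keyed by `(root_seed, n, r)` through a chained multiplicative
hash (exact in double arithmetic, collision-free over the design space).
Two consequences:

* **Common random numbers.** The key excludes the effect size and the
  grid, so all five effects and all three grids of a given `(n, r)` reuse
  the identical base Normal sample; the treatment shift is added
  afterwards and the grid only changes the discretisation. Differences
  between scenarios are therefore differences between *conditions*, not
  sampling noise, and the control-arm summaries agree exactly across
  mechanisms.
* **Order independence.** No state is carried between repetitions or
  scenarios, so serial and permuted execution produce bit-identical
  results, and a rerun with the same configuration reproduces every output
  byte (the manifest timestamp aside).

Datasets at different sample sizes come from separate substreams rather
than nested subsets; nesting across `n` is not part of the contract.

## The estimators

All three fits share the contract: point estimate of the arm coefficient,
standard error, two-sided CI and p-value at level α (default 0.05), and a
`converged` flag. A non-converged fit carries `NA`s and is excluded
listwise from every performance measure, with the missing count reported.

**MLR.** For the saturated two-group design the OLS coefficient is the
difference in arm means and its SE the pooled-variance two-sample formula;
inference uses `t` with `n − 2` df. Degenerate case: zero within-arm
variance in both arms gives `se = 0`; the fit is flagged missing rather
than reporting an infinite test statistic.

**Tobit.** The two-sided censored-Normal log-likelihood treats scores
strictly inside (0, 100) as exact observations and boundary scores as
left-/right-censored (status assigned by exact equality with a bound,
which is well-defined on discretised data). The likelihood is maximised
over `(β₀, β₁, log σ)` — the `log σ` parameterisation keeps the scale
positive — by BFGS with the analytic score, starting from the OLS solution
(`β` at OLS, `σ` at the 1/n-divisor residual SD), relative convergence
tolerance 1e−12, at most 200 iterations. Observations are aggregated to
unique `(arm, score)` cells first, so one likelihood evaluation costs
O(k), which is what makes 5000-repetition scenarios cheap. SEs come from
the inverse observed information (numerically differentiated analytic
score at the optimum); intervals and p-values use Normal quantiles —
standard MLE asymptotics, indistinguishable from `t` at the design's
n ≥ 100. `converged = FALSE` on optimiser failure, non-positive-definite
information, or an all-censored sample. Note the discretised interior
scores violate the exact-observation assumption; the resulting
overestimation on coarse grids is a finding, not a bug.

**Median regression.** For the intercept + arm design the LAD objective
separates by arm, so the exact minimiser is the pair of within-arm sample
medians and the effect estimate their difference. With an even arm size
the LAD solution set is an interval `[y_(m/2), y_(m/2+1)]`; we take the
conventional midpoint (R's `median`). This tie-break matters on coarse
grids, where the interval endpoints can be a whole score gap apart: the
midpoint convention is symmetric (an LP vertex solver would land on either
endpoint depending on pivoting, which averages to the same place but is
not reproducible), and it is the convention consistent with the mean
estimates this design produces. SEs use the asymptotic sparsity method:
`Var(β̂₁) = [4 f(0)²]⁻¹ (1/n₀ + 1/n₁)` with `f(0)` an Epanechnikov kernel
density estimate of the fit residuals at zero. The bandwidth is the
Hall–Sheather rule at the median, `h = n^(−1/3) z_{α/2}^(2/3)
(1.5 φ(0)²)^(1/3)` on the probability scale, mapped to the residual scale
by `(Φ⁻¹(0.5 + h) − Φ⁻¹(0.5 − h)) · min(sd, IQR/1.349)` — the default of
the quantile-regression software family. Inference is `t`-based with
`n − 2` df. Degenerate residual spread (`min(sd, IQR/1.349) = 0`) or a
non-positive density estimate flags the fit missing; on the 4-level grid
this occurs in roughly 0.1–0.4% of repetitions depending on the scenario,
and such repetitions are what the missing-fit tally counts.

## Performance measures

With `x` the predefined latent shift and `x̂ᵢ` the per-repetition
estimates (converged only, `n_valid` of them):

* bias `= mean(x̂ᵢ) − x`; MCSE `= EmpSE/√n_valid`;
* EmpSE `= sd(x̂ᵢ)` (n−1 divisor); MCSE `= EmpSE/√(2(n_valid − 1))`;
* MSE `= mean((x̂ᵢ − x)²)`, which equals `bias² + (n−1)/n · EmpSE²`
  exactly — an identity the tests assert to 1e−10;
* coverage `= mean(ci_low ≤ x ≤ ci_upp)` (closed interval), rejection rate
  `= mean(p ≤ α)` (inclusive), each with binomial MCSE. At 5000
  repetitions the coverage MCSE at 0.95 is ≈ 0.003, giving the
  0.944–0.956 band quoted for the design.

Bias is computed against the *latent* shift even though discretisation
attenuates the observable group difference (except at `x = 0`, the truth
on the observed scale is unknowable); part of every method's "bias" on
coarse grids is therefore a discretisation artefact by construction, and
the observed-scale group differences are tabulated separately so the two
sources can be told apart.

## Problem sizes used in the tests

Unit and property tests run reduced designs (tens of repetitions, n of
100–400) chosen so the whole suite completes in well under a minute while
still exercising every code path; the reproduction tests
(`test-acceptance.R`) run their scenarios at the full 5000 repetitions,
which the cell-aggregated Tobit likelihood keeps to a few seconds per
scenario. Comparisons against published scenario means use the run's own
Monte Carlo SE (`3 · EmpSE/√5000`) as tolerance, never a fixed constant.

## Known limitations

* The median-regression SE reproduces the *family* of sparsity estimators,
  not any one implementation bit-for-bit; bandwidth internals differ
  between packages, so coverage and Type I error for Median may differ
  slightly from other software at the third decimal, though the gross
  inflation on coarse grids (Type I error near one half at k = 4, driven
  by `P(arm medians differ) ≈ 1/2` combined with a small sparsity SE) is
  implementation-independent.
* Tobit Wald intervals use Normal quantiles; at n < 100 a `t` correction
  would be visible.
* The framework simulates location shifts on a homoscedastic latent Normal
  only; conclusions do not transfer to strongly skewed preference-based
  utilities, where a difference in means may not even be the right
  estimand.
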