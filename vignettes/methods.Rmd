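---
title: "Methods: design, generator, statistics and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, generator, statistics and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices behind `phycofactor`: what
the package assumes about the experiment, how the synthetic generator is
parameterized and what it deliberately does not emulate, the exact
statistical formulas used, and the small numerical conventions
(standardization, quantiles, tie-breaking, seeding) that make results
reproducible to the byte.

## The experimental design

The package models a one-factor-at-a-time (OFAT) screening study over
five cultivation factors:

| factor                | levels                      | baseline |
|-----------------------|-----------------------------|----------|
| `co2_pct`             | 5, 7, 9, 11 %               | 9        |
| `temperature_C`       | 10, 20, 30, 40 °C           | 30       |
| `light_colour`        | white, red, green, blue     | white    |
| `light_intensity_lux` | 2000, 2500, 3000, 3500 lux  | 3000     |
| `pH`                  | 5, 7, 9, 11                 | 7        |

Each factor is swept through its four levels while the other four sit
at baseline, giving five series of four conditions. The five series
share the all-baseline condition, so there are 16 *distinct* conditions
per genus; with the default three replicates the baseline condition
accumulates 15 observations per genus (five series × three replicates).
Five genera (*Chlorella*, *Botryococcus*, *Chlamydomonas*,
*Tetraselmis*, *Closterium*) are run in parallel, and nine responses
are measured per culture: biomass plus the proximate-composition panel
(lipid, protein, fibre, ash, moisture, nitrogen-free extract, sodium,
potassium).

**Assumption.** OFAT cannot estimate interactions; every analysis in
the package (MANOVA by series, per-factor importance, per-condition
optimum lookup) is interpreted conditionally on the other factors being
at baseline. This mirrors how such screening studies are reported, but
it means a true optimum off the OFAT axes is invisible by design.

## The synthetic generator

`generate_experiment()` draws each response from a deterministic
response surface plus independent Gaussian noise, clipped to a
physical range:

```
y = clip( base + Σ_f effect_f(x_f) + ε ),   ε ~ N(0, noise_sd²)
```

- **Numeric factors** contribute a quadratic *peak* effect
  `A · max(0, 1 − ((x − opt) / w)²)` centred at a planted optimum
  `opt`, with half-width `w` equal to the largest distance from the
  optimum to any level, so no level's effect is truncated to exactly
  zero by accident.
- **Light colour** contributes a per-level offset: the optimal colour
  gets the full amplitude `A` and the others get `0.3 A`, `0.15 A`
  and `0`.
- **Amplitudes** follow a 3 : 1 dominance ratio: the planted dominant
  factor gets `0.30 × range(y)`, every other factor `0.10 × range(y)`,
  where `range(y)` is the response's physical range (e.g. biomass
  0.2–2.1 g/L).
- **Noise** defaults to `noise_sd = 0.015 × range(y)` per observation.
  This value comes from an a-priori power calculation, not from tuning:
  with three replicates, the closest competitor level sits about
  `0.25 A` below the optimum, and at 1.5 % relative noise the
  probability of recovering both the dominant factor and the planted
  optimum across seeds exceeds the package's stated guarantees (≥ 95 %
  and ≥ 90 % respectively) with margin.
- **Planted truths** differ from the all-baseline condition in at most
  one factor (for example red light for protein and lipid, 7 % CO₂ for
  fibre), so recovery is non-trivial but well-posed under OFAT.
  `planted_truth()` returns the full table of dominant factors and
  optimal conditions so tests and users can score recovery exactly.

**What the generator emulates:** the location and dominance structure
of factor effects, genus-to-genus variation in peak height and
position, replicate noise, and hard physical bounds.

**What it does not emulate:** factor interactions, temporal dynamics
of a culture, heteroscedastic or correlated measurement error across
the nine responses, and compositional closure (the proximate fractions
are *not* constrained to sum to 100 %). It is a validation instrument
for the analysis chain, not a biological model.

## MANOVA

For responses `Y` (n × p) grouped by a factor with `g` levels,
`sscp()` forms the hypothesis and error SSCP matrices `H` and `E`. The
four statistics are computed from the eigenvalues `λᵢ` of `E⁻¹H`
(obtained from the symmetrized Cholesky form for numerical stability):

- Wilks' `Λ = Π 1/(1 + λᵢ) = det(E)/det(H + E)`, with Rao's F
  approximation;
- Pillai's trace `V = Σ λᵢ/(1 + λᵢ)`,
  `F = ((2n + s + 1)/(2m + s + 1)) · V/(s − V)`;
- Hotelling–Lawley trace `T = Σ λᵢ`,
  `F = T · 2(sn + 1)/(s²(2m + s + 1))`;
- Roy's largest root `λ₁`, upper-bound
  `F = λ₁ (df_e − r + df_h)/r` with `r = max(p, df_h)`,

where `s = min(p, df_h)`, `m = (|p − df_h| − 1)/2` and
`n = (df_e − p − 1)/2`. These formulas were frozen only after verifying
they reproduce `stats::summary.manova` exactly, and the test suite
keeps that oracle plus the determinant-ratio identity and the `p = 1`
reduction to the univariate ANOVA F. `manova_by_genus()` reports both
per-genus and pooled ("all") tests because the two answer different
questions: whether a factor moves the response vector *within* a genus,
versus across the panel; neither subsumes the other.

## The composite model score

`w_new(r2_train, r2_val, mae, rmse, mse)` implements

```
S = r2_train + r2_val        Err = mse + rmse + mae
d = |r2_train − r2_val|      C = (1 − d)/(1 + d)
X = (S / Err) · C            w_new = X / (1 + X)
```

with the edge policy: `X ≤ 0` scores 0 (never selectable), `Err`
below 1e-12 with positive `S·C` scores 1, and a vanishing error with
non-positive skill is an error. The function is a pure function of the
five supplied numbers — it does not re-derive RMSE from MSE — because
published comparison tables round each metric independently, and
`benchmark_metrics()` carries exactly those rounded values. The
recomputed scores agree with the published column to within ±0.005.

## Features, standardization and splitting

`encode_features()` produces eight columns: the four numeric factors
plus four one-hot light-colour indicators (all four levels kept,
scikit-learn style). `standardize()` uses the **population** (1/n)
standard deviation, so the two-point sample `{2, 4}` maps to
`{−1, +1}`; constant columns get scale 1 rather than NaN. Train
statistics are frozen and applied unchanged to validation data.
Keeping all four indicators makes a linear design rank-deficient with
an intercept; predictions remain estimable because the indicators sum
to one on every valid row, and that specific `predict.lm` warning is
silenced — no other warning is.

## Cross-validation and model selection

`make_folds(n, k, seed)` assigns folds by a seeded permutation.
Within each fold the standardization and any reduction branch
(none / PCA / correlation-ranked selection) are re-fit on the training
part only, so no information leaks from the held-out fold. Fold
metrics are aggregated by averaging the five metrics across folds and
scoring `w_new` **on the fold-mean metrics** (not averaging per-fold
scores); this matches how a single comparison table per model is
reported. `grid_search()` scores every (family, hyper-parameter row,
branch) candidate, skips candidates that error, and breaks exact ties
by first occurrence in roster → grid → branch order, which makes
selection deterministic. Model fits are seeded per fold
(`seed + fold`), and all tree libraries run single-threaded
(`num.threads = 1`, `nthread = 1`) so results do not depend on
scheduling.

The roster covers nine families. Two are worth noting: gradient
boosting uses `xgboost` with GBM-style defaults (`eta = 0.1`,
`max_depth = 3`) since no dedicated GBM package is assumed, and
AdaBoost.R2 (Drucker's linear-loss variant over `rpart` stumps with
case weights and weighted-median prediction) is implemented in the
package because no maintained CRAN implementation for regression
exists.

## Importance and optima

`importance_values()` extracts raw impurity importances (ranger
`variable.importance`, xgboost Gain, rpart `variable.importance`);
`impurity_importance()` pools encoded columns back to their source
factor **before** normalizing to sum 1, so a categorical factor's four
indicators are credited to one factor. A profile whose raw total is
zero is returned as all-zero with `no_signal = TRUE` rather than
renormalized. `average_profiles()` averages per-genus profiles and
renormalizes. `find_optimal_conditions()` groups observations by the
full factor combination and returns the arg-max of the mean response;
exact ties resolve to the design-order lexicographically smallest
condition.

## Report conventions

Five-number series summaries use `stats::quantile()` type 7 (linear
interpolation between order statistics, the R default). The
correlation matrix covers the four numeric factors and nine responses;
zero-variance columns yield `NA` rows/columns with a warning instead
of being dropped silently.

## Pipeline and determinism

`run_pipeline()` executes generate → MANOVA → model selection →
importance → report, each stage wrapped so a failure names its stage.
All randomness flows from four named seeds in the config
(`generation`, `split`, `cv`, `model`); CSVs are written with fixed
column order; two runs of the same config are byte-identical (verified
by MD5 in the test suite). Importance uses the selected family when it
is tree-based and falls back to a random forest otherwise, since
impurity importances only exist for tree ensembles.

## Problem sizes

The defaults were exercised at the scale they target: 300-row
experiment tables (5 genera × 20 series-conditions × 3 replicates),
3–5-fold cross-validation, grids of a few rows per family, and
50-seed recovery studies. A full default pipeline run completes in a
few seconds on one core.
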