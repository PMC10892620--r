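---
title: "MLR QSAR modelling and validation: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MLR QSAR modelling and validation: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarmlr)
```

## The model

qsarmlr models a compound's activity (pIC50, the negative decadic log of
a molar IC50) as a linear function of precomputed molecular descriptors,

$$y_i = \beta_0 + \sum_{j=1}^{p} \beta_j x_{ij} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

fitted by ordinary least squares. The assumptions are the usual ones:
a linear mean structure in the chosen descriptors, homoscedastic
independent errors, and a training series that spans the descriptor
space of interest. The package does not select descriptors; the subset
is an input, and with n compounds you should keep p well below n (the
bundled case study runs p = 10 on n = 27, which is aggressive and is
exactly why the validation suite matters).

The solver is a Householder QR decomposition of the intercept-augmented
design matrix, written in the package rather than delegated, with
coefficients by back-substitution and leverages as row sums of squares
of the thin Q factor. `stats::lm` serves purely as an independent
oracle in the test suite. Descriptors are used on their raw scales —
no standardization — so coefficients are directly comparable to
published model equations; the orthogonal decomposition keeps this
stable even when column magnitudes differ by seven orders (topological
indices ~1e6 against Mulliken charges ~1e-1). Fitted values are
invariant under affine rescaling of any descriptor, which the tests
assert.

Numerical choices:

* rank deficiency is declared when the smallest singular value of the
  design falls below 1e-10 times the largest, and the error names the
  offending column(s);
* a fit is treated as exact ("perfect") when RSS ≤ 1e-20 · SSY, in
  which case the Fisher ratio is reported as `Inf` with a warning and
  standardized residuals as `NA` (a flagged degenerate assessment, not
  an error);
* fitting requires n > p + 1, leave-one-out requires n > p + 2 so every
  reduced fit stays overdetermined.

## The validation suite

`validate_qsar()` reports the classical QSAR statistic set. Most
definitions are standard; four conventions deserve explicit statement
because more than one circulates in the literature, and the package
fixes the variant that reproduces the bundled case study's original
report:

* **Quality factor** `Q = R / s_y` (multiple correlation over the
  activity standard deviation), not R/SEE. On the bundled data
  0.942/0.224 = 4.21, matching the originally reported 4.224; the
  R/SEE convention would give ≈ 9.8.
* **Probable error** `PE = 0.6745 (1 − R²)/√n`, the classical probable
  error of a correlation coefficient. It reproduces the reported 0.015
  and 6PE = 0.09.
* **"PRESS" has two meanings.** In part of the QSAR validation
  literature the quantity tabulated as PRESS is numerically the
  ordinary residual sum of squares of the full fit, and the derived
  "R²cv" = 1 − RSS/SSY is then just R². The bundled study's summary
  table is of this kind: its PRESS (0.147) equals the RSS and the sum
  of squared per-compound residuals of its prediction table, its
  S_PRESS = √(RSS/(n−p−1)) = 0.096 equals the SEE, and its
  "R²cv" = 0.89 equals R². The package therefore reports both the
  residual-based fields (`rss`, `press_fit`, `press_ratio`, `s_press`)
  and the genuine leave-one-out fields (`press_loo`, `q2_loo`), and
  never conflates them.
* **PSE** is exposed as `press_loo / n` (mean squared LOO prediction
  error); this is an interpretation, since the quantity is often named
  but rarely defined.

Leave-one-out is computed with the exact OLS identity
$e_{(i)} = e_i / (1 - h_i)$; `loo_residuals(fit, "refit")` performs the
n explicit refits instead, and the equality of the two routes is
asserted in the tests at 1e-8 relative tolerance on random instances.

**A known discrepancy.** On the bundled 27-compound matrix the exact
leave-one-out computation gives PRESS_LOO = 0.636 and Q² = 0.511. The
originally reported cross-validated Q² for this model is 0.631. We
could not recover that value from the printed data under any LOO
convention we examined (classic 1 − PRESS/SSY = 0.511; squared
correlation between observed and LOO-predicted activities = 0.618;
leave-one-out means in the denominator = 0.515), while every other
reported statistic — coefficients, R², F, SSY, RSS, all 27 predicted
values, h\* — reproduces to printed precision. The package reports the
exact value and documents the difference rather than matching the
report; the corresponding acceptance expectation is deliberately left
failing as a record of the discrepancy.

## Y-randomization

`y_randomization()` draws uniform random permutations of the activity
vector (strict permutations, not resampling with replacement), refits
the same descriptors, and records r, R² and the shortcut Q² per trial.
Only the activity order is permuted; the design matrix is asserted
unchanged across trials. Under the null of no structure–activity
relationship, E[R²] = p/(n−1) (0.385 at the case study's dimensions),
which the tests verify against 2,000-trial runs. The default is 50
trials, the size of the original robustness check.

The chance-correlation summary is
$cR_p^2 = R\sqrt{R^2 - \langle R^2_r \rangle}$. Two variants of the
scrambled term circulate: the mean of the squared scrambled
correlations, and the square of the mean scrambled correlation. With
the original run's summary values (R² = 0.887, mean scrambled
R² = 0.364, mean scrambled R = 0.594) the first gives 0.681 — the
value originally reported — and the second 0.689. The first
(`as_used`) is the package default; both are always returned, and a
negative radicand is flagged invalid rather than clipped.

## Applicability domain

The domain is leverage-based: compound i is flagged when its hat
diagonal exceeds the warning leverage $h^* = m(p+1)/n$. The multiplier
defaults to m = 2.5, the value used in the case study (giving
h\* = 2.5·11/27 = 1.0185, reported there at coarser rounding as 1.01);
the more common m = 3 is available via `hstar_multiplier`. Residual
outliers are flagged outside ±3 standard units, the conventional
Williams-plot band. Standardized residuals divide by the fit's SEE by
default; internally studentized residuals (dividing by
SEE·√(1−h)) are available with `studentized = TRUE`, since published
Williams plots rarely state which was used. For new compounds the
leverage is the quadratic form $x^\top(X^\top X)^{-1}x$ evaluated
through the training QR factor; the training centroid attains the
minimum 1/n exactly.

Note that with p + 1 = 11 parameters on n = 27 compounds, h\* > 1 while
every leverage is ≤ 1: no training compound can exceed the threshold.
The case study's "no outliers" finding is real but partly a geometric
consequence of its p/n ratio — one reason the residual band matters.

## Reactivity descriptors

From a frontier-orbital pair (eV): gap Eg = E_LUMO − E_HOMO, hardness
η = Eg/2, softness δ = 1/(2η), chemical potential
μ = (E_HOMO + E_LUMO)/2, electrophilicity ω = μ²/(2η). Units are eV
end-to-end (δ in 1/eV); no Hartree conversion is applied anywhere.
`rank_by_reactivity()` orders a batch by ascending gap (most reactive
first), breaking ties lexicographically by compound id, and flags the
most negative chemical potential as most stable. For the bundled
designed-compound table this puts 11f most reactive and 11b least,
with the softness ordering the exact reverse of the hardness ordering.

Inputs with E_HOMO ≥ E_LUMO are rejected by default. The bundled
training table prints its two orbital columns transposed (a
transcription artifact preserved verbatim, like the implausible `mw`
cell of compound 7h, because fixture fidelity to the printed source
takes priority and neither column enters the activity model);
`orbital_order = "swap"` corrects such pairs with a warning when the
columns are consumed for reactivity.

## The synthetic-data generator

`generate_qsar_data()` emulates the statistical structure the analysis
assumes: p continuous descriptors from a correlated Gaussian
(exchangeable pairwise correlation, per-column location/scale) and
activity from a known linear model plus Gaussian noise, deterministic
under a seed. `ptp1b_mimic_spec()` instantiates the case study's
dimensions: n = 27, the ten model descriptors at their empirical
column means and standard deviations, exchangeable correlation 0.3 (a
mild, realistic level of collinearity), and the published equation as
the true coefficient vector. The noise level, `noise_sd = 1.3`, was
calibrated once by Monte Carlo so the expected fitted R² at these
dimensions is ≈ 0.89; because the synthetic descriptor cloud lacks the
strong *structured* collinearity of the real columns (which nearly
cancels the raw-scale signal), the calibrated noise is much larger
than the real residual scale. The generator is therefore a
plausibility and parameter-recovery harness, not a reproduction of
real descriptor tables: it does not produce heavy-tailed or integer
descriptor distributions, block correlation between related
descriptors, or chemically realizable descriptor combinations, so a
passing recovery test says the *pipeline* is correct, not that real
data meet the model's assumptions.

## Problem sizes and determinism

The test suite keeps all simulations at desk scale: random-instance
cross-checks use n ≤ 50, p ≤ 12; the analytic permutation null is
verified with 2,000 scrambling trials on a 27 × 10 design;
parameter-recovery harnesses use 200–300 replicates. Every stochastic
test and every report is seedable, and a pipeline run with a fixed
seed produces byte-identical JSON output.

## Known limitations

* No descriptor-subset selection, regularization, or robust
  regression: the descriptor set is taken as given.
* No external test-set or bootstrap validation (the case study has no
  held-out set); leave-one-out is the only resampling offered.
* The applicability domain is leverage-only; distance-to-model and
  density approaches are out of scope.
* Descriptor computation from structures (SMILES/SDF, quantum
  chemistry) is out of scope; the package consumes numeric tables.
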