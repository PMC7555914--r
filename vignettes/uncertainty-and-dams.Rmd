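---
title: "Diagnostic accuracy measures as functions of measurement uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic accuracy measures as functions of measurement uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damu)
```

## The problem

A quantitative diagnostic test dichotomizes a continuous measurand at a
threshold `d`: values above `d` are called test-positive. Two distinct
sources of spread determine how well this works — the biological variation
of the measurand in the diseased and non-diseased populations, and the
analytical imprecision of the measurement procedure, summarized by its
standard measurement uncertainty `u`. Laboratory quality management reasons
about `u`; clinical decision-making reasons about sensitivity, specificity
and their derived accuracy measures. `damu` connects the two: every measure
is an explicit, differentiable function of `u`, so its sensitivity to
analytical quality can be computed, plotted and compared between two
procedures measuring the same measurand.

## Model and assumptions

The package assumes:

* a gold-standard reference classifies disease status without error;
* the measurand (or a transform of it; the package is unit-agnostic) is
  normal in each population: diseased `N(μ_D, σ_D)`, non-diseased
  `N(μ_D̄, σ_D̄)`, with known parameters — estimation from samples is out of
  scope;
* measurement error is normal, unbiased on the working scale, and
  homoscedastic across the threshold range, so observed values in
  population P are `N(μ_P, sqrt(σ_P² + u²))`;
* classification is "measurement above `d` ⇒ positive". The inverse
  orientation is obtained by swapping the two populations in
  `population_pair()`, not by a flag, so every formula keeps a single form.

Under these assumptions `Se(d)` and `Sp(d)` are normal tail probabilities of
the *observed* distributions, and all twelve measures in `dam_measures()`
are algebraic functions of `(Se, Sp, v)` and, for the risk, the five loss
constants. All normal probabilities route through one internal
erf/erfc-based primitive pair (`erf()`, `erfc()`, `erfcinv()` are exported),
so the closed forms agree with their error-function expressions to machine
precision.

## Parameters that matter

| parameter | meaning | units | default |
|---|---|---|---|
| `mu_d`, `sigma_d` | diseased-population mean/SD | measurand units | none (user input) |
| `mu_nd`, `sigma_nd` | non-diseased mean/SD | measurand units | none |
| `v` | prevalence | probability | none |
| `u` | standard measurement uncertainty | measurand units | none |
| `d` | diagnostic threshold | measurand units | optional |
| `l0, l_tn, l_fn, l_tp, l_fp` | expected losses | one common scale | none |

The loss constants carry no sign or normalization constraint; "lower risk is
better" is fixed by the fact that `optimize_threshold("R", ...)` minimizes.
The bundled `case_study_fixture()` holds a normalized oral glucose tolerance
test setting: log-glucose expressed in units of the non-diseased SD, giving
`μ_D = 2.99, σ_D = 0.75, μ_D̄ = 0, σ_D̄ = 1`, prevalence `v = 0.067`,
threshold `d = 2.26` (the 11.1 mmol/L criterion), uncertainties
`u = 0.023` and `0.23` (CVs of 1% and 10%), and losses `(1, 0, 100, 0, 76)`.
The fixture takes the uncertainties as given on the normalized scale; no
helper is provided for folding a bias component into `u`, since the
combination rule is not part of the model.

## Numerical choices

**Threshold grids.** Curves and optimizer seeds use
`[min(μ) − 6σ_max_eff, max(μ) + 6σ_max_eff]` (512 points for curves), which
covers more than 6 effective SDs of both populations, so curve endpoints
reach their corners to better than 1e-9.

**Optimization.** `optimize_threshold()` is deterministic and
derivative-free: a 1000-point coarse grid locates the global basin (guarding
against secondary optima of the risk under extreme loss ratios), then
Brent's method refines within the bracketing grid cells to 1e-6 in `d`. The
four objectives are smooth, so this is reliable without derivatives. A flat
objective — e.g. Youden's index when the two populations coincide — reports
the interval midpoint with a `non_unique` flag instead of failing.

**Derivatives.** `∂Se/∂u` and `∂Sp/∂u` are analytic (chain rule through the
effective SD), and every other measure's derivative follows by the chain
rule through its closed form in `(Se, Sp)`. A finite-difference fallback
(central difference with one Richardson extrapolation step,
`h = max(1e-6, 1e-3·u)`) serves as an internal cross-check; the measures
depend on `u` only through `u²`, so the stencil may cross zero and the
derivative at `u = 0` is exactly 0.

**Boundaries.** Division-by-zero cases follow fixed conventions
(`Sp = 1 ⇒ LR+ = DOR = ∞`; `Se = 1 ⇒ LR− = 0`), and indeterminate `0/0`
cases return `NaN` with a warning, never an error, so sweeps and optimizers
may pass through boundaries. Infinite thresholds return exact limit values.

**Inversion accuracy.** `se_given_sp()`, `sp_given_se()` and `roc()` invert
a tail probability. In double precision a probability within ~1e-16 of 1
carries no usable information about its quantile, so round-trip accuracy
necessarily degrades for thresholds in the extreme tails (beyond roughly 6
effective SDs of the relevant mean) — no algorithm can do better there. The
package forms the upper-tail quantile directly from `Se` (never `1 − Se`) to
avoid the avoidable half of this loss; within 5 effective SDs of the
respective population mean the round trips are exact to better than 1e-11.

**PROC curve.** The predictive ROC curve composes PPV with the inverse of
NPV and has no elementary form. `proc_points()` therefore parametrizes the
curve by the threshold, `d ↦ (1 − NPV(d), PPV(d))`, which is identical on
the monotone range and needs no nested root-finding; `npv_inverse()`
(bracketed root-finding) exists to validate the literal composition. For
extreme parameter combinations NPV can be non-monotone in `d`; the
parametrized curve is then still well defined, while `npv_inverse()` raises
an error rather than silently choosing a branch.

## The case study as a test bed

The test suite and `scripts/acceptance.R` exercise the package on the OGTT
fixture: the eight optimal thresholds (four objectives × `u ∈ {0.023, 0.23}`)
and their relative differences under the `(m1 − m2)/m1` convention, the
closed-form AUC against adaptive quadrature of the ROC integral over an
18-point parameter sweep, inverse round trips, analytic-versus-numerical
derivatives for all twelve measures, and the equal-variance symmetry of the
Youden-optimal threshold. These computations are parameter-level and run in
seconds; no sampling is involved, so all results are exactly reproducible.

A qualitative pattern worth noting, visible in `sweep_measure()` over
`u ∈ [0.023, 0.23]` at the conventional threshold: the relative changes of
AUC, Se, Sp, ODA, PPV, NPV, ED and CZ are, as a group, several-fold smaller
than those of DOR, LR+, LR−, J and the risk. The comparison is a group-level
one — the Euclidean distance individually moves more than Youden's index —
so the corresponding test asserts the ordering of group means, not each
pair.

## Limitations

* Parameters are taken as known; no estimation, confidence intervals or
  sample-based (empirical) ROC curves.
* The uncertainty model is normal and homoscedastic; heteroscedastic
  uncertainty would require a variance-stabilizing transform upstream.
* Bias is not modelled separately from `u`.
* Optimization is over the threshold only, one objective at a time.
* What passes on the binormal fixture shows internal consistency of the
  closed forms, not that any real assay's log-measurand is exactly normal;
  with skewed or heavy-tailed populations the closed forms do not apply.
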