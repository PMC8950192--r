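---
title: "Methods: cosolvency modeling, unit codes and error criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosolvency modeling, unit codes and error criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jacree)
```

## The model and its assumptions

The Jouyban–Acree model writes the log-solubility of a drug saturated in a
binary solvent mixture as the lever-rule combination of the two mono-solvent
log-solubilities plus a temperature-scaled interaction polynomial:

$$\ln x_{m,T} = w_1 \ln x_{1,T} + w_2 \ln x_{2,T} +
  \frac{w_1 w_2}{T}\sum_{i=0}^{np} J_i (w_1 - w_2)^i,
  \qquad w_2 = 1 - w_1 .$$

Assumptions built into this package's treatment:

* **The mono-solvent anchors are data, not parameters.** The measured
  $x_{1,T}$, $x_{2,T}$ enter the response; each distinct temperature must
  therefore carry both pure-solvent records. We require measured anchors
  rather than interpolating them, which would add an unstated model.
* **Errors are multiplicative.** The model is linear in $\ln x$, so the
  estimation assumes (and the generator produces) additive Gaussian noise on
  the log scale, making unweighted OLS the natural estimator.
* **Pure-solvent records carry no regression information.** At $w_1 \in
  \{0,1\}$ both the regressors and the response are identically zero, so
  those rows are excluded from the fit (they would only inflate the residual
  degrees of freedom) but retained in back-calculation and in the error
  criteria, whose $N$ counts all points in a set.
* **Natural logarithms throughout; no observation weights.**

With all $J_i = 0$ the model reduces to ideal log-linear mixing
(`yalkowsky_predict()`), which is also the exact behavior of
`predict_ln_solubility()` at the composition endpoints for any fit.

## Estimation and term pruning

`fit_ja()` solves the no-intercept least-squares problem by QR
factorisation; an independent brute-force normal-equations solver is kept in
the test suite as an oracle, and the two agree to better than ten
significant digits on randomised fixtures. Standard errors and two-sided
t-test p-values use $\mathrm{df} = n_\mathrm{rows} - n_\mathrm{retained}$.

`np` is the upper summation index: `np = 2` (the default, and the common
choice in practice) estimates $J_0, J_1, J_2$; `np = 4` estimates five
terms. When `prune = TRUE`, backward elimination repeatedly drops the single
retained term with the largest p-value above `alpha` (ties resolved by
dropping the higher-order term) and refits until everything retained is
significant or one term remains. One-at-a-time elimination with refitting is
the minimal procedure consistent with published prunings in which only the
highest-order term falls away; pruned coefficients are reported as exactly
zero. On synthetic data whose true $J_3 = 0$, this procedure drops $J_3$ and
keeps the three strong terms in about 97% of seeds at the default noise
level.

Rank-deficient designs (e.g. a single repeated mixed composition) and
underdetermined systems fail with named errors rather than silently
switching to a pseudoinverse.

## The nine unit codes

Solvent composition can be expressed on mole, mass or volume basis; solute
concentration as mole fraction, molarity or g/L — nine codes in total
(`unit_code()`). `convert_dataset()` re-expresses a dataset in any code:

* Basis conversions are the exact algebraic maps between mole, mass and
  volume fractions of the *solute-free* mixture. Volume fractions use the
  volume-additive (ideal-mixing) convention from pure-solvent densities:
  the data give no mixing-volume information, and this convention is exactly
  invertible. A supplied mixture-density table is used only to default a
  missing saturated-solution density, never for volume fractions.
* Solute conversions route through the drug mole fraction. Molarity needs
  the saturated-solution density:
  $C = 1000\, x_d\, \rho_\mathrm{sat} / \bar{M}$ with
  $\bar{M} = x_d M_d + (1 - x_d)(x_1 M_1 + x_2 M_2)$ the mean molar mass of
  the saturated ternary. When $\rho_\mathrm{sat}$ is absent and needed,
  conversion fails loudly and lists the offending records — silently guessing
  a density would corrupt every downstream comparison. g/L is exactly
  molarity times the drug molar mass.

Two structural consequences are asserted as tests rather than stated as
folklore: *(i)* because g/L and molar data differ by the constant factor
$M_d$, and the response subtracts the lever-rule term with $w_1 + w_2 = 1$,
the code pairs (2,3), (5,6), (8,9) give identical $J$, MRD%, RMSD₂ and E₂,
and E₁/RMSD₁ ratios equal to $M_d$ exactly; published constant tables that
show small differences between such pairs reflect intermediate rounding of
the converted data, an artifact this package avoids by converting in double
precision and never rounding before serialisation. *(ii)* relabelling the
solvents maps $J_i \mapsto (-1)^i J_i$ with unchanged predictions.

## Error criteria

Five criteria compare back-calculated with experimental solubilities: MRD%
(mean relative deviation × 100), RMSD₁ and E₁ (root-mean-square and mean
absolute deviation, arithmetic scale, in solubility units), RMSD₂ and E₂
(the same on the log scale, dimensionless). **The relative and arithmetic
mean deviations use absolute values.** The printed definitions omit the
bars, but the quantities are described and used as deviations, and a signed
mean would cancel to zero for any bias-free fit — a useless fit-quality
criterion. This is the one place the implementation must choose against the
literal formula; it is deliberate and prominent.

Internally all metrics are stored unscaled; the presentation factors
(10⁵·RMSD₁, 100·RMSD₂) exist only in printing/reporting. MRD%, RMSD₂ and E₂
are invariant under a common positive rescaling of both vectors; RMSD₁ and
E₁ are homogeneous of degree one. `correlate_metrics()` correlates each
criterion against a reference (MRD% by default) across datasets, flagging
(never dropping) constant criteria whose correlation is undefined. On
synthetic suites whose solubility magnitudes span many orders of magnitude,
the log-scale criteria track MRD% nearly perfectly (Spearman ≈ 0.99) while
the arithmetic ones are dominated by the magnitude itself (≈ 0.06) — the
quantitative form of the argument that MRD% is the most comparable
criterion across heterogeneous systems.

## The synthetic world

`generate_dataset()` produces data with exactly the statistical structure
the analysis assumes: van't Hoff mono-solvent anchors
$\ln x_\mathrm{pure}(T) = A + B/T$, the model evaluated forward with known
$J$ on a composition grid at each temperature, and $\mathcal N(0,
\sigma^2)$ noise added on the log scale to mixed records. Defaults are the
stated world of the package's tests: three temperatures (298.2, 308.2,
318.2 K), an eleven-point grid including both endpoints (33 records), an
ethanol/water-like solvent pair (M = 46.07/18.02 g/mol, ρ = 0.789/0.997
g/mL), a 250 g/mol drug, $J = (897.693, -1417.112, 1671.752)$ K — a real
published three-term fit — and $\sigma = 0.05$ (≈5% multiplicative error,
typical inter-laboratory reproducibility for solubility work). Anchors are
noise-free by default because the model treats them as known inputs; a flag
makes them noisy for robustness probes.

The saturated-solution density is the volume-additive solvent-mixture
density times $(1 + \kappa x_d)$ with $\kappa = 0.1$, so mole-fraction ↔
molar conversions are non-trivial yet exactly invertible (conversions always
use the stored per-record density). For generation directly in molar or g/L
space the $x_d$ in the coupling is a proxy computed from the mixture
density; since conversions only ever consume the stored value, round trips
remain exact regardless.

**What a green test establishes — and what it does not.** The generator
emulates the *structure* of literature collections (grid designs, magnitude
ranges spanning a 10⁶ molar ratio, composition skew, noise), not any
specific measured system: no activity-coefficient physics, no
temperature-dependent real densities, no correlated measurement error.
Green property tests certify the estimator, the conversions and the metrics
against known ground truth; they do not certify agreement with any
particular laboratory dataset, and the published per-drug error tables
(computed from 79 literature sets not packaged here) are out of scope.

An important impossibility shapes the noise-free tests: data generated
exactly in one code's space are *not* exact in another. Changing the
composition basis warps the lever-rule term, and changing the solute unit
adds $\ln(1000\rho_\mathrm{sat}/\bar M)$, a composition-dependent offset
outside the model family — this is precisely why the unit choice affects
fit quality at all. The noise-free fixed-point criterion is therefore
checked per code, each in its own space, where all five metrics vanish to
~10⁻¹⁴.

## Suite presets and numerical choices

`make_paper_like_suite()` draws $J$, noise, drug mass and anchor levels from
ranges bracketing published fits, on mass-uniform grids. The
`"wide-magnitude"` preset stratifies pure-solvent solubility levels across
$[10^{-7}, 0.3]$ so that any suite of ≥2 datasets provably spans the ≥10⁶
molar-solubility ratio seen between the extremes of real collections
(stratification, not rejection sampling, keeps the property deterministic).
The `"skewed"` preset uses a heavy cosolvent ($M_1/M_2 = 78.13/18.02
\approx 4.3$) with *equal* solvent densities: the equal densities are a
deliberate idealisation that makes volume ≡ mass fraction, isolating the
molar-mass mechanism by which a mass-uniform grid becomes mole-skewed (mean
mole fraction ≈ 0.30 here) — the documented explanation for mole-basis
codes fitting systematically worse.

Other numerical choices: temperatures are kelvin-only internally (the model
divides by absolute $T$; the CSV reader converts a Celsius column on
ingest); $w_2$ is never stored; endpoint and temperature matching use
relative tolerances of 10⁻¹² and 10⁻⁹; `inject_outlier()` does not
re-validate, because the classic ×100 alteration can push a mole-fraction
datum past 1 — downstream conversion still validates and fails loudly.
Perturbation experiments refit the model on the altered dataset, since the
criteria respond both through the changed residual and through the shifted
coefficients.

## Known limitations

* Volume fractions assume ideal mixing volumes; excess-volume corrections
  are out of scope.
* Backward elimination inherits the usual caveats of stepwise inference;
  the reported p-values are not selection-adjusted.
* With zero residual degrees of freedom (saturated designs) standard errors
  and p-values are undefined (`NaN`) and pruning is a no-op.
* Temperature extrapolation beyond the data's range, ternary solvent
  extensions, and robust/weighted regression variants are not supported.
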