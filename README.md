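# jacree

Cosolvency modeling of drug solubility in binary solvent mixtures with the
Jouyban–Acree model, for pharmaceutical scientists who need to correlate
saturation data across temperatures and solvent compositions — and to
understand how the *choice of concentration units* and of *error criterion*
changes what the model appears to tell them.

## The model

For a drug saturated in a mixture of solvents 1 and 2 at absolute
temperature *T*,

```
ln x_m,T = w1·ln x1,T + w2·ln x2,T + (w1·w2 / T) · Σ_{i=0}^{np} J_i·(w1 − w2)^i
```

where `x1,T`, `x2,T` are the measured mono-solvent solubilities, `w1`,
`w2 = 1 − w1` the solute-free solvent composition, and the `J_i` (units of
kelvin) capture non-ideal mixing. With all `J_i = 0` the model collapses to
the ideal log-linear mixing rule (Yalkowsky), `ln x_m = w1·ln x1 + w2·ln x2`.
The `J_i` are estimated by ordinary least squares of the excess-log response
`ln x_m,T − w1·ln x1,T − w2·ln x2,T` on the regressors
`w1·w2·(w1 − w2)^i / T` (no intercept), optionally with backward elimination
of terms whose two-sided p-value exceeds α = 0.05.

Both the solubility and the composition can be expressed in several units.
The package implements all nine combinations as **codes 1–9**:

| composition basis \ solute unit | mole fraction | molar | g/L |
|---|---|---|---|
| mole fraction   | 1 | 2 | 3 |
| mass fraction   | 4 | 5 | 6 |
| volume fraction | 7 | 8 | 9 |

Back-calculated solubilities are scored with five criteria: MRD% (mean
relative deviation, %), RMSD₁/RMSD₂ (root-mean-square deviation on the
arithmetic/log scale) and E₁/E₂ (mean absolute deviation on the
arithmetic/log scale). MRD%, RMSD₂ and E₂ are scale-invariant; RMSD₁ and E₁
carry the solubility unit, which is why the g/L columns of a multi-code
comparison are exactly the molar columns times the drug's molar mass.

## Worked example

```r
library(jacree)

cfg <- generator_config(seed = 42)   # ethanol/water-like system, 5% log-noise
ds  <- generate_dataset(cfg)
res <- run_code_analysis(ds, code = 4, np = 2)
print(res$fit)
print(res$metrics)
```

```
<ja_fit> 'synthetic', code 4, np = 2, n = 27 rows
           J       se           p retained
J0   911.253  26.6984 7.44657e-22     TRUE
J1 -1411.927  53.3279 2.83508e-19     TRUE
J2  1684.292 122.9615 7.70918e-13     TRUE
<metrics_report> N = 33
  MRD%  : 4.024
  RMSD1 : 0.000254186   (1e5 * RMSD1 = 25.42)
  RMSD2 : 0.0557734   (100 * RMSD2 = 5.577)
  E1    : 0.000122628
  E2    : 0.0399935
```

The generator's true coefficients were (897.693, −1417.112, 1671.752) K; at
5% multiplicative noise the fit recovers them within ~1–2 standard errors,
and the mean back-calculation error is 4% — typical of literature fits. A
multi-dataset, all-code study:

```r
suite <- make_paper_like_suite(10, seed = 1)   # mass-uniform grids
study <- run_full_study(suite, codes = 1:9)
print(study)
```

```
<study_summary> 10 dataset(s) x 9 code(s); 0 failure(s)
Overall MRD% per code:
 code n_datasets mean_mrd_percent sd_mrd_percent
    1         10            6.624          2.809
    2         10            6.474          2.784
    3         10            6.474          2.784
    4         10            3.106          1.377
    5         10            3.065          1.236
    6         10            3.065          1.236
    7         10            3.573          1.539
    8         10            3.395          1.402
    9         10            3.395          1.402
```

Two structural facts of the comparison are visible: the solute unit barely
matters (codes 2/3, 5/6, 8/9 are identical by scale invariance), while the
composition basis does — these datasets are uniform in *mass* fraction, so
in *mole* fraction the grid is skewed away from 0.5 (ethanol vs water molar
masses) and codes 1–3 fit about twice as badly. `composition_skew()`
quantifies that skew per dataset, and `perturb_and_compare()` shows every
criterion responding to a single ×10 outlier:

```r
p <- perturb_and_compare(ds, index = 6, factor = 10, code = 4)
```

```
<perturbation_result> 'synthetic', record 6: 0.001333587 -> 0.01333587 (x10), code 4
                before      after
mrd_percent 4.02429589 1.3234e+01
rmsd_arith  0.00025419 2.0567e-03
rmsd_log    0.05577342 3.8235e-01
e_arith     0.00012263 5.9223e-04
e_log       0.03999348 1.5944e-01
```

Command-line entry points (`inst/scripts/ja-study`, `ja-simulate`,
`ja-perturb`) wrap `cli_study()`, `cli_simulate()` and `cli_perturb()` for
batch use on CSV/JSON dataset files.

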