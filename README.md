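# kcalib

Body-size calibration of insect thermal summation constants, for forensic
entomologists estimating the minimum postmortem interval (PMI) from insect
evidence.

## The problem

When immature insects collected on a cadaver are reared to adult emergence,
their age at collection is obtained by subtracting the thermal time
accumulated during laboratory rearing from the species' thermal summation
constant *k* — the physiological age at emergence in accumulated degree-days
(ADD) or degree-hours (ADH). But *k* is the central point of a species: it
systematically misrepresents unusually small and large individuals, because
size and physiological age at emergence are correlated (negatively in
necrophagous and predatory carrion insects, positively in parasitoids).
Regression models of *k* against size exist for only two species, so a direct
size calibration is rarely possible.

`kcalib` implements a calibration that needs no "*k* versus size" dataset.
From the species' published thermal summation model (*k*, its standard error
*s*<sub>e</sub>, the number of experimental temperatures *m*) and a
literature body-length range [*l*<sub>min</sub>, *l*<sub>max</sub>], the
calibrated value for an individual of length *l* is

```
K_c(l) = k - s_e * sqrt(3 m) / (l_max - l_min) * (l - (l_max + l_min) / 2)
```

(sign of the second term flipped for positively correlated species). This is
the reduced major axis (model II) regression line implied by two
approximations: the spread of individual "true *k*" values is estimated by
`sd(k_t) ≈ s_e * sqrt(m) / 2`, and a length sample spanning the range is
treated as an arithmetic sequence, so `sd(l) ≈ sqrt(3) (l_max - l_min) / 6`
and `mean(l) ≈ (l_max + l_min) / 2`. The RMA slope is then
`sign(cor) * sd(k_t) / sd(l)`, which collapses to the formula above.

The package provides:

* the calibration formula and line construction (`calibrate_k`,
  `calibration_line`), with the approximation lemmas (`sd_true_k`,
  `sd_length_approx`, `mean_length_approx`);
* reduced major axis regression (`rma_fit`, `rma_loss`);
* thermal-time arithmetic: individual true *k*, degree-day accumulation over
  temperature logs, age at collection, ADD/ADH conversion, and a minimal
  linear thermal summation fitter (`true_k`, `accumulate_dd`,
  `age_at_collection`, `fit_thermal_summation`);
* a packaged registry of ready-made calibration lines for eleven forensically
  important carrion insects of central Europe (`species_registry`,
  `species_formula`, `infer_m`, `choose_size_range`);
* the validation pipeline — half-millimetre length classes, class medians,
  MSE comparison of the RMA / calibrated / constant-*k* models, extreme-size
  subsets, ANOVA with LSD post hoc tests and Benjamini–Hochberg adjustment
  (`validate_models` and friends);
* a synthetic-data generator emulating the two beetle development datasets
  the formula was validated on (`default_spec`, `generate_records`).

## Worked example

A teneral *Necrodes littoralis* of 16.0 mm is reared for 120 h at a constant
20 °C before emergence:

```r
library(kcalib)

nl   <- species_entry("Necrodes littoralis")
line <- species_formula(nl)
line
#> Kc(l) = 710.82 - 12.05 l  [ADD], valid for l in 15-25 mm (negative correlation)

kc <- calibrate_k(nl$params, nl$range, 16, nl$correlation_sign)
round(kc, 2)
#> 518.08

rearing <- accumulate_dd(temperature_log(1:120, rep(20, 120), step_hours = 1),
                         nl$params$d0)   # D0 = 8.5 degC
rearing
#> 57.5

age <- age_at_collection(kc, rearing)
round(age, 2)
#> 460.58
round(dd_to_days(age, 20, nl$params$d0), 1)
#> 40.1
```

The calibrated physiological age at emergence of this small beetle is
518.08 ADD — about 48 ADD above the species constant 469.89 ADD — and its
age at collection is 460.58 ADD, roughly 40.1 days' worth of development at
a constant 20 °C.

The validation pipeline on a synthetic emulation of the *N. littoralis*
dataset, restricted to unusually small and large beetles:

```r
rec <- generate_records(default_spec("N_littoralis"), seed = 42)
validate_models(rec, nl$params, extremes = TRUE)
#> Model comparison on per-class squared errors
#>   MSE:  constant = 1541, kc = 15.53, rma = 9.796
#>   ANOVA: F = 36.52 on (2, 45) df, p = 3.768e-10
#>   LSD pairwise (BH adjusted):
#>     constant vs kc: diff = 1525, p = 2.721e-09, p_adj = 4.081e-09
#>     constant vs rma: diff = 1531, p = 2.476e-09, p_adj = 4.081e-09
#>     kc vs rma: diff = 5.738, p = 0.9779, p_adj = 0.9779
```

The calibrated line tracks the data about as well as an RMA line fitted to
the data themselves, and both leave errors two orders of magnitude below the
constant-*k* model on extreme-sized individuals.

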