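---
title: "Calibrating thermal summation constants by body size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating thermal summation constants by body size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcalib)
```

## The model

The thermal summation constant $k$ of an insect species is its mean
physiological age at adult emergence, in accumulated degree-days (ADD) or
degree-hours (ADH) above a lower developmental threshold $D_0$. Individual
insects vary around $k$, and this variation correlates with adult body size.
`kcalib` calibrates $k$ for an individual of length $l$ (mm) as

$$K_c(l) \;=\; k \;-\; \frac{s_e\sqrt{3m}}{l_{\max}-l_{\min}}
\left(l - \frac{l_{\max}+l_{\min}}{2}\right),$$

where $s_e$ is the standard error of $k$ from the species' thermal summation
regression, $m$ the number of constant temperatures behind that regression,
and $[l_{\min}, l_{\max}]$ a literature body-length range for the species or
population. For positively correlated species (parasitoids) the sign of the
second term flips.

The line is a reduced major axis (RMA, model II) regression line obtained
without individual-level data, by estimating its two ingredients:

* **Spread of the individual "true $k$"**: $sd(k_t) \approx s_e\sqrt{m}/2$
  (`sd_true_k`). The standard error of a regression mean shrinks roughly
  like $1/\sqrt{m}$ relative to the underlying spread; this inverts that
  relation with a factor calibrated to the thermal summation design.
* **Spread and centre of lengths**: a sample spanning the species range is
  treated as an arithmetic sequence, giving
  $sd(l) \approx \sqrt{3}\,(l_{\max}-l_{\min})/6$ (`sd_length_approx`, the
  continuous-uniform limit) and $\bar l \approx (l_{\max}+l_{\min})/2$
  (`mean_length_approx`).

The RMA slope magnitude is $sd(k_t)/sd(l)$, which is exactly
$s_e\sqrt{3m}/(l_{\max}-l_{\min})$, and the line is anchored at
$(\bar l, k)$. Two structural consequences are used as invariants
throughout the test suite: $K_c$ at the range midpoint is $k$, and the total
spread $K_c(l_{\min}) - K_c(l_{\max})$ is $s_e\sqrt{3m}$.

### Assumptions

* The length / true-$k$ relationship is linear over the range, with the
  correlation sign fixed by ecology (negative for necrophagous and predatory
  species, positive for parasitoids). The sign is carried as data in the
  species registry and can be overridden per entry.
* $[l_{\min}, l_{\max}]$ actually represents the natural size variation of
  the reference population. When several sources disagree,
  `choose_size_range` applies the broadest-range rule (widest single
  source). We read "broadest" as the widest *single* source rather than the
  envelope across sources, since each published range is one population's
  variation while an envelope mixes populations; the widest-single-source
  reading also matches every selected range in the packaged registry. Width
  ties are broken toward the larger $l_{\max}$ — a convention of this
  package (consistent with the registry's own selections), flagged with a
  warning because no published rule covers ties.
* The approximations are asymptotic in the number of length classes. The
  exact population sd of an $n$-point arithmetic sequence is
  $(l_{\max}-l_{\min})\sqrt{(n+1)/(12(n-1))}$, so the uniform-limit
  approximation undershoots by the factor $\sqrt{(n-1)/(n+1)}$: about 4.7%
  at $n = 21$ (a half-millimetre grid over a 10 mm range) and below 1% only
  beyond roughly 100 points. The formula inherits this bias: with half-mm
  measurement grids its slope magnitude is a few percent larger than the
  sequence-exact RMA slope would be. The test suite asserts this
  convergence profile rather than pretending the 21-point error is
  negligible.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `k`, `se` | ADD or ADH | per species | from the published thermal summation model; ADH = 24 × ADD, and converting units scales the whole line by 24 (`convert_unit`) |
| `m` | count | per species | not printed in published formula tables; recovered by brute-force inversion of the published slope over $m \in \{2,\dots,30\}$ (`infer_m`), with a warning above 0.5% relative residual and an error on ties |
| `l_min`, `l_max` | mm | per species | broadest literature range, or the dataset's own min/max in the validation pipeline |
| `correlation_sign` | – | `"negative"` | `"positive"` only for parasitoids |
| `D0` | °C | none | shipped only for the two beetle species with published thresholds (11.7 °C and 8.5 °C); otherwise a required user input |
| `grid` | mm | 0.5 | the length measurement accuracy; lengths snap to this grid before binning |
| `low`, `high` | percentile | 33, 66 | extreme-size cutoffs in the validation pipeline |

## Degenerate inputs and numerical conventions

* $s_e = 0$ is a well-defined limit: the spread term vanishes and
  `calibrate_k` returns $k$ with a "no calibration possible" note rather
  than an error.
* Lengths outside the size range are extrapolated on the same line with a
  warning and a flag — casework insects can slightly exceed literature
  ranges, and a hard error would push users to silently widen ranges.
  A zero-width range is rejected at construction.
* RMA: standard deviations use the population (divide-by-$n$) convention to
  match the sd/correlation algebra above (the slope is unaffected).
  $sd(x)=0$, $sd(y)=0$ and $r=0$ are errors — $\mathrm{sign}(0)$ has no
  value, and guessing a sign would silently corrupt everything downstream.
  The product loss `rma_loss` is reported as the summed *unsigned* residual
  product: the raw product $(y-\hat y)(x-\hat x)$ has the constant sign
  $-\mathrm{sign}(\beta_0)$ for every point, so the unsigned version is the
  quantity that is non-negative, zero iff collinear, and minimized by the
  closed-form fit (verified against a brute-force grid in the tests).
* Degree-day accumulation is rectangular (per reading, clamped at $D_0$),
  not trapezoidal: the linear-threshold convention, and identical to
  trapezoidal at the constant temperatures development studies use. ADD is
  canonical; ADH is derived by ×24 exactly once, avoiding double
  conversions.
* Lengths snap to the nearest grid value with ties at the bin midpoint
  rounding half up, making class membership deterministic for synthetic
  data that can land exactly on .25 offsets.

## The validation pipeline

Individual records are grouped into length classes (one class per distinct
half-mm value) summarized by the **median** true $k$; most individuals sit
near the mean length, and medians prevent the crowded central classes from
dominating. Three models are compared on the class medians: an RMA line
fitted to the medians, the $K_c$ line built from the species constants and
the *dataset's own* min/max lengths, and the constant-$k$ horizontal line.
Fit is the unweighted mean squared error over classes — weighting by class
size would reintroduce the bias the medians removed.

The extreme-size analysis keeps records strictly below the 33rd and strictly
above the 66th length percentile. Percentiles use linear interpolation
between order statistics (`quantile` type 7, the common default; the
realized thresholds are attached to the result so users can compare them
against published cutoffs). Squared errors are compared by one-way
**unpaired** ANOVA with model as the factor, then Fisher's LSD post hoc test
(pairwise two-sided $t$-tests on the pooled within-group variance) with
Benjamini–Hochberg adjustment of the three $p$-values. Class-level squared
errors are treated as the observations, consistent with carrying the
median-only datasets through all analyses; the unpaired design is the
classical reading of "ANOVA + LSD", and is recorded here as a convention
since a paired layout would also be defensible.

## The synthetic-data generator

Real development datasets behind this methodology are not publicly
deposited, so the generator (`default_spec`, `generate_records`) emulates
their statistical structure: 173 *Creophilus maxillosus* records over
15–24 mm and 954 *Necrodes littoralis* records over 12–22 mm, lengths on a
0.5 mm grid, true $k$ negatively correlated with length.

* **Lengths**: a normal centred at the range midpoint with sd
  $\sqrt{3}(l_{\max}-l_{\min})/6$, truncated to the range and snapped to the
  grid. This reproduces the crowded central classes and sparse extremes that
  motivated class medians. A uniform-grid mode exists to exercise the
  arithmetic-sequence lemma.
* **True $k$**: the species calibration line recomputed on the dataset
  range, plus Gaussian residuals — the simplest model consistent with a
  linear conditional mean and an assumed marginal spread.
* **Residual sd by variance decomposition**:
  $\sigma_\varepsilon^2 = sd(k_t)^2 - \beta^2\,\mathrm{var}(l)$, targeting
  the marginal spread $sd(k_t) = s_e\sqrt{m}/2$. Here $\mathrm{var}(l)$ is
  the *exact* variance of the grid-snapped truncated-normal length
  distribution (computed from its probability mass function), not the
  nominal uniform-limit value: with the nominal value the decomposition is
  algebraically zero whenever the generating line is the $K_c$ line, and
  because truncation shrinks the realized length sd by ~18%, the generated
  marginal spread would undershoot its target. With the exact variance the
  identity $\beta^2\mathrm{var}(l) + \sigma_\varepsilon^2 = sd(k_t)^2$
  holds by construction, and the Monte-Carlo check in the tests confirms
  the marginal sd within 3% at $n = 10^5$. If a user-supplied line is
  steeper than the target spread allows, the residual clamps to zero with a
  warning.
* One seed drives both the length and residual draws, so records are
  bit-reproducible.

What the generator does **not** emulate: sex effects, temperature-dependent
size plasticity, between-population variation, non-Gaussian residuals, and
any skewness or heavy tails the real length distributions may have. Passing
pipeline tests on synthetic data therefore demonstrate internal consistency
of the method — that the calibrated line beats constant $k$ on extreme sizes
*when the assumed structure holds* — not fidelity to any particular real
dataset.

Simulation sizes used by the test suite were chosen to keep estimator noise
well below the asserted tolerances: 100 seeds at the emulated dataset sizes
for pipeline orderings and slope-recovery bias, 50 seeds for per-run
recovery rates, $10^5$ records for marginal-sd checks, and $10^4$-point
sequences for the RMA/formula agreement bound.

## The species registry

`species_registry()` ships eleven species as an editable CSV (mirrored as
JSON): thermal constants with units, the selected size range and its source,
ecology and the implied correlation sign, optional $D_0$, and the published
line coefficients kept solely for cross-checking. Users analysing other
populations should substitute the range for the closest geographic
population and re-derive the line; changing the range moves the line but
$K_c$ at the new midpoint is always $k$.

One registry entry is deliberately *not* reproduced as published: the
parasitoid *Nasonia vitripennis* line is printed with a positive slope but
an intercept equal to $k + |\beta|\,\bar l$ — the negative-correlation
construction — so the printed line never passes through $k$ anywhere on its
size range. `species_formula` computes the line from first principles
(intercept $k - |\beta|\,\bar l \approx 1209.1$ ADH), reproduces the printed
slope magnitude, and leaves the printed intercept as a documented
inconsistency rather than guessing the intended correction.

## Known limitations

* The formula is derived, not fitted: its validation here is against
  synthetic data with the assumed structure, and published support comes
  from laboratory populations of two beetle species from one region.
* The ecology → correlation-sign mapping is an assumption encoded as data;
  species with unusual life histories may violate it.
* `fit_thermal_summation` propagates the slope standard error to $k$ by the
  first-order delta method; published models may have computed their
  standard errors differently, so mixing sources can be mildly
  inconsistent.
* The approximation bias of the arithmetic-sequence sd (a few percent at
  realistic class counts) steepens calibration lines slightly; at the range
  midpoint it cancels, and at the range limits it is bounded by the same few
  percent of the total spread $s_e\sqrt{3m}$.
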