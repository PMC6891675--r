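---
title: "Calibrating honey physicochemical properties from Raman spectra"
author: "RamanHoney package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating honey physicochemical properties from Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Honey quality is graded by a panel of physicochemical parameters — pH,
moisture, total soluble solids (TSS, °Brix), free/lactonic/total acidity
(meq kg⁻¹), electrical conductivity (mS cm⁻¹), Redox potential (mV),
hydroxymethylfurfural (HMF, mg kg⁻¹) and ash (g/100 g) — each normally
measured by a separate wet-chemistry reference method. Dispersive Raman
spectroscopy offers a single fast, reagent-free measurement: the 200–2000
cm⁻¹ fingerprint region carries sugar skeleton modes, ring modes of HMF
and phenolics, C–H/C–O–H sugar envelopes, protein C–N modes, and
water/carbonyl bands. **RamanHoney** implements the complete chemometric
workflow that turns replicate Raman spectra plus reference property values
into validated per-property calibration models.

## The model

Each property is modeled independently by PLS1 regression fitted with the
NIPALS algorithm. Given the preprocessed calibration matrix $X$ (spectra
in rows) and response $y$ (centered, scaled to unit variance), component
$a$ is computed as

$$
w_a = \frac{X_a^\top y_a}{\lVert X_a^\top y_a\rVert},\qquad
t_a = X_a w_a,\qquad
p_a = \frac{X_a^\top t_a}{t_a^\top t_a},\qquad
q_a = \frac{y_a^\top t_a}{t_a^\top t_a},
$$

followed by deflation $X_{a+1} = X_a - t_a p_a^\top$,
$y_{a+1} = y_a - q_a t_a$. After $A$ components the regression vector is
$b = W (P^\top W)^{-1} q$, and predictions are
$\hat y = \bar y + s_y\,(x - \bar x)^\top b$. NIPALS PLS1 needs no random
initialization, so the entire pipeline is deterministic given its seed.
PLS1 (one model per property) was chosen over PLS2 because the ten
responses have very different signal strengths and deserve independent
complexity selection; scores are mutually orthogonal by construction, and
at full rank the fit coincides with ordinary least squares (both facts are
exercised by the test suite against independent oracles).

## Workflow and its decisions

`runPipeline()` executes, per property:

1. **Trimming** to the working window, default the closed interval
   [201, 2000] cm⁻¹. A stated working range like "201–2000" is read as
   inclusive on both ends; this is documented rather than self-evident,
   since half-open conventions exist.
2. **Kennard–Stone 90/10 split.** Greedy maximin selection on Euclidean
   distances seeds with the most distant pair and repeatedly adds the
   point farthest (in min-distance) from the selected set; ties break
   toward the lower row index, making the split reproducible. By default
   the split is *group-aware*: selection runs on per-sample mean spectra
   and whole replicate triplets are assigned together, because splitting
   replicates of one honey across calibration and validation would leak
   sample identity into validation. `groupAware = FALSE` restores a plain
   row-wise split of the replicate-expanded matrix.
3. **Preprocessing recipe.** Default order: alignment → ALS baseline →
   Savitzky–Golay smoothing → area normalization → SNV → autoscaling.
   First-derivative and log10 steps are available but disabled by default
   (log10 cannot follow SNV or derivatives, which produce negatives).
   Stateful steps (alignment reference, column means/sds) are fitted on
   calibration rows only and applied unchanged to validation rows.
4. **LV selection** by leave-five-out cross-validation: a seeded
   permutation of the calibration rows is cut into blocks of five, and
   $\mathrm{SECV}(A) = \sqrt{\sum r^2 / n}$ over pooled held-out
   predictions is minimized (first minimum on ties).
5. **Final fit and validation statistics** (next section).

Recipe parameters and rationale:

| step | defaults | why |
|---|---|---|
| align | integer shifts, ±5 points, reference = mean calibration spectrum | corrects replicate grid misalignment; sub-sample interpolation is out of scope |
| baseline (ALS) | λ = 1e5, p = 0.001, 10 iterations | standard asymmetric-least-squares penalized smoother; stiff enough to ignore peaks, flexible enough for fluorescence-like backgrounds |
| smooth (SG) | window 11, order 2 | reproduces polynomials exactly; the interior 5-point order-2 kernel is the classic (−3, 12, 17, 12, −3)/35 |
| normalize | area (row sum = 1) | removes overall intensity/collection-efficiency differences |
| snv | sample sd (n−1 denominator) | either sd convention is defensible; the choice is stated so results can be reconciled |
| autoscale | per-column mean/sd of calibration rows | gives every wavenumber equal a-priori weight; "centering or autoscaling" are both supported, autoscale is the default |

### Cross-validation refitting

Within each CV fold the trailing centering/autoscaling and the PLS model
are refit on the retained rows only. The row-local treatments (baseline,
smoothing, normalization, SNV, derivatives, log10) are deterministic
functions of each spectrum alone, so their output cannot depend on which
fold a row is in; they are computed once per calibration set. The
alignment reference — the mean calibration spectrum — is likewise held
fixed across folds: removing five of ~500 rows perturbs the mean by far
less than one grid step of structure, and integer-shift estimates are
insensitive to it. This makes the double loop exact for the stateful
steps that matter (the scalers, which genuinely change per fold) at a
fraction of the cost; the CV routine is verified against an independently
coded double-loop oracle that uses the Krylov-subspace form of PLS.

## Validation statistics

With $d = \hat y - y$:

* $\mathrm{SEC} = \sqrt{\sum d^2 / (n - A - 1)}$ on the calibration set —
  degrees of freedom charge the $A$ latent variables and the intercept.
* $\mathrm{bias} = \bar d$ and
  $\mathrm{SEP} = \sqrt{\sum (d - \bar d)^2/(n-1)}$ on the validation
  set. SEP is invariant to a constant prediction offset, SEC is not; the
  asymmetry is intentional and standard.
* $R^2$ is the squared Pearson correlation between $y$ and $\hat y$
  (affine-invariant); the explained-variance form $1 - SSE/SST$ is
  available via `rSquared(..., method = "explained")`.
* The paired t statistic $t = \bar d \sqrt n / s_d$ is compared with the
  Student-t quantile at $n-1$ degrees of freedom. The default band is the
  one-sided 95% quantile — at validation sizes in the hundreds this is
  the familiar ±1.65 — with two-sided and other levels configurable.

## The synthetic data generator

No public honey Raman database accompanies this problem, so the package
ships a generator that emulates the structure the analysis assumes; it is
first-class, tested code, not a fixture. For sample $i$:

$$
x_i(w) = \sum_b \Big(\alpha_b + \textstyle\sum_p c_{bp} z_{ip}\Big)
  e^{-(w - \mu_b)^2/2\sigma_b^2} + \mathrm{poly}_i(w) + \varepsilon
$$

* **Bands** are Gaussians at the midpoints of the vibrational-assignment
  ranges of honey spectra (lineshapes are not otherwise specified in the
  chemistry; Gaussians keep the model analytic). Base amplitudes sketch a
  typical honey spectrum with the dominant sugar envelope near 920 cm⁻¹.
* **Couplings** act on z-scored property values so magnitudes are
  comparable across properties, and each property owns a disjoint set of
  bands so its signal is identifiable.
* **Properties** are drawn from truncated normals (clipping, not
  resampling — clipping keeps each draw a pure function of its substream
  position) with pooled means/sds and min/max envelopes from an
  eight-municipality survey of Campeche honey; two structural constraints
  are imposed: total acidity = free + lactonic, and TSS = 100 − moisture
  plus 0.3% jitter (sugars and water are near-complementary).
* **Nuisance terms**: a per-sample cubic baseline with small random
  coefficients (fluorescence-like), additive N(0, 0.02 a.u.) noise per
  point, a N(0, 0.02 a.u.) per-replicate offset, and a random integer
  grid shift of at most ±2 points per replicate.
* **Seeding**: one root seed feeds named substreams (property draws,
  baseline, shifts, replicate offsets, noise), so adding a band or a
  property never perturbs unrelated draws.

### Choosing coupling magnitudes

Coupling strengths were fixed a priori by a matched-filter argument. A
band of width σ sampled at spacing $\delta$ has profile energy
$\lVert g\rVert^2 \approx \sigma\sqrt{\pi}/\delta$, so a coupling $c$
against i.i.d. noise of sd $\eta$ gives a per-spectrum signal-to-noise
ratio $\mathrm{SNR} = c\,\lVert g\rVert/\eta$ and an upper bound
$R^2 \approx \mathrm{SNR}^2/(1+\mathrm{SNR}^2)$. The defaults place
moisture, TSS, the three acidities and Redox potential at SNR ≳ 20
(near-perfect recovery), pH and electrical conductivity near SNR 2
(usable but imperfect models), HMF near 1.4, and ash near 0.6 — so the
ten models reproduce the qualitative predictability ordering observed for
real multifloral honey, with ash worst. These are design constants of the
generator: they were set once from this calculation and are not tuned.

The generator's `"noiseless"` scenario zeroes every nuisance term, making
spectra an exactly linear, noise-free function of the standardized
properties. In that regime the pipeline must recover every property with
$R^2_{val} \ge 0.999$; the acceptance checks use a purely linear recipe
(centering) there, because area normalization and SNV divide by
row-dependent norms and would introduce a small nonlinearity into an
otherwise exact system.

### What the generator does *not* emulate

Real spectrometer data have heteroscedastic shot noise, cosmic-ray
spikes, wavelength-dependent instrument response, fluorescence that
saturates and bleaches, and chemically overlapping bands whose amplitudes
respond nonlinearly and collinearly to composition. Passing tests on the
synthetic scenario therefore demonstrate that the *algorithms* are
implemented correctly and that the pipeline recovers known structure at
realistic noise — not that any particular accuracy will be achieved on
new instrument data.

## Numerical choices and degenerate inputs

* Serialization (CSV, loadings) prints 12 significant digits, enough for
  bit-stable round-trips at the printed precision; report tables print 4
  decimals.
* SNV and autoscaling refuse zero-variance rows/columns with explicit
  errors; log10 names the offending cell; ALS requires ≥ 3 points;
  Savitzky–Golay windows must be odd and no wider than the row.
* A constant response yields the degenerate 0-component model
  (coefficients 0, intercept = the constant) rather than an error; a
  response orthogonal to the predictors raises a rank error naming the
  component. During cross-validation on exactly low-rank data, fold
  models truncate at the last informative component and the SECV curve is
  extended flat, so large candidate counts remain comparable.
* Kennard–Stone ties (both in the seed pair and in the maximin step)
  break toward the lowest row index; fold assignment uses a seeded
  permutation cut into consecutive blocks.
* The wavenumber grid defaults to 900 uniform points over [201, 2000]
  cm⁻¹. A dispersive instrument quoting 1.55 cm⁻¹ resolution over this
  range would yield ~1160 points; survey descriptions of this kind of
  data nonetheless fix 900 values, so the grid length is a configurable
  parameter with 900 as the documented default rather than a derived
  quantity.

## Problem sizes

The reference scenario is 189 samples × 3 replicates on a 900-point grid
(567 spectra, 510,300 intensities). The full ten-property pipeline on
this size — including leave-five-out CV over ~100 folds and up to 10
candidate components per property — completes in a few minutes on one
core; the unit-test suite works on reduced sizes (≈ 24 samples,
300-point grids) chosen to exercise identical code paths at a fraction of
the cost.

## Known limitations

* Integer-only alignment: sub-grid shifts are rounded, by design.
* One shared recipe across properties by default. Per-property recipes
  are supported (call `runPipeline()` per property with a different
  `recipe`), but no automatic per-property recipe search is provided.
* A single LV count per property, chosen by SECV minimum; conventions
  that report separate calibration and validation LV counts for one model
  are not reproduced.
* `rSquared()`'s Pearson form can be optimistic when predictions are
  affinely miscalibrated; the paired-t/bias statistics are the guard
  against reading it alone.

## A minimal session

```{r example}
library(RamanHoney)
ds <- simulateHoneyDataset(syntheticConfig(nSamples = 60, seed = 1))
run <- runPipeline(ds$spectra, ds$properties,
                   propertyNames = c("moisture", "total_acidity", "ash"),
                   lvMax = 8, seed = 1)
run
reportTable(run, "report.csv")
exportLoadings(run, "loadings.csv")
```
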