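---
title: "Methods: from collar fixes to a grazing-intensity map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from collar fixes to a grazing-intensity map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazint)
```

## The estimation problem

A grazing sheep is a moving point source of forage removal. Given a fix
stream $(P_1, T_1), (P_2, T_2), \dots$ at a 2-minute interval, daily
intake $I_Z$ known from body weight, and the grazing day $T_Z$, we want
the spatial field $F(x)$ of grams removed per square metre. The package
estimates $F$ in three stages — zone exclusion, constant-rate allocation,
covariate modelling — each of which is usable on its own.

### Intake model

Daily dry-matter intake of grazing sheep is 2–4% of body weight; at a
dry-to-fresh mass ratio of about 0.39 this corresponds to fresh intake of
7.6% of body weight, the default of `intake_model()`. Both routes are
implemented (`daily_intake(mode = "fresh" | "derived")`) and must agree
within 5% or the model is rejected: the shipped defaults give
$0.03/0.39 = 0.0769$ versus $0.076$, a 1.2% discrepancy we accept as
rounding in the source constants. Note the constants are deliberately
exposed rather than hard-coded: the published per-class daily amounts
(3.4–4.5 kg for 40–60 kg animals) are not exactly reproducible from 7.6%
of the class bounds, so users can recalibrate.

Only a fraction $a$ of the grazing day is spent feeding (published range
84.92–90.19%; default 0.86). Two rate conventions are provided.
*Literal*: $V = I_Z/T_Z$, so a segment of duration $T_i$ removes
$V \cdot T_i$. *Corrected* (default): the feeding rate is
$I_Z/(T_Z a)$ and a segment feeds for $a T_i$ of its duration, so its
intake is again $I_Z T_i / T_Z$ — the corrected pieces telescope to
$I_Z$ over a full day. The correction therefore changes the meaning of
the rate (grams per *feeding* second), not the day total; what does
change totals is zone exclusion, which removes non-feeding time before
allocation.

### Allocation on the grid

The analysis grid is square with 13 m cells ($S = 169\,$m²); each segment
carries a rectangular buffer of half-width 3 m with flat ends (a
zero-length segment degenerates to the square of the same half-width —
6 m side — the limit of the corridor as length goes to zero). In the
default *conservative* mode each segment's intake is distributed over the
cells its buffer intersects, weighted by exact overlap area
(Sutherland–Hodgman clipping + shoelace area), so
$\sum_i F_i S = \sum_i I_i$ to machine precision — the property the test
suite asserts at $10^{-6}$ g over 100 random trajectories.

The published closed form
$$F = \frac{I_Z\, T_i\, C_i}{\sum C_i \cdot T_Z \cdot S}$$
(with $T_i$ the summed dwell of segment midpoints in cell $i$ and $C_i$
their count) is implemented verbatim as `mode = "literal_eq5"`. Because
it weights each cell by both dwell time and point count, it double-counts
occupancy and does not conserve $I_Z$ except in degenerate cases (all
mass in one cell, where both modes give $F = I_Z/S$; or the symmetric
two-cell case, $1000/(4 \cdot 169) = 1.4793$ g/m²). We keep it for
fidelity and comparability, but conservative is the default for maps.
Whether the formula's $T_i$ means per-cell dwell or per-segment interval
is ambiguous in the source; per-cell summed dwell was chosen as the only
reading under which $\sum C_i$ normalisation is meaningful.

### Zone exclusion

Rest (pen, midday shade) and drinking clusters contribute position
records but no grazing. The kernel density surface (Gaussian kernel,
truncated at $4h$, normalised to integrate to the fix count) is graded
into five classes; connected components of grade ≥ 4 become candidate
clusters classed by rules: mean within-cluster fix speed < 0.05 m/s and
dwell ≥ 30 min → rest; containing the water point → drinking; otherwise
grazing. Override polygons win over the rules — mirroring the original
workflow, where zones were labelled by inspection, and covering cases the
rules cannot (the pen cluster's mean speed is inflated by
departure/return passes, so `run_pipeline()` passes the known pen
location as a rest override). Exclusion is idempotent, and surviving
fixes carry a `run` id so segmentation never bridges an excluded gap.

**Bandwidth.** Silverman's rule on the fix coordinates is the default for
`kernel_density()` because it is standard and scale-aware, but on a full
grazing day it yields ~150 m bandwidths that smear dwell clusters into
travel paths. For zone *detection* the pipeline uses 20 m — the scale of
the collar's positioning error plus the physical size of pen and water
sites — and natural-breaks grading (`"jenks"`, a deterministic
quantile-seeded 1-D k-means; exact Fisher–Jenks programming is $O(kn^2)$
and unnecessary for 5 classes), which isolates the heavy-tailed dwell
densities far better than quantile grading. Quantile remains
`grade_density()`'s default scheme for descriptive five-grade maps.

### The feature screen

Eight candidate predictors attach to each retained segment: duration
$T$, distance $C$, slope $P$, elevation $E$, aspect $D$, NDVI, weight
$S$, temperature $F$. Terrain and NDVI are sampled at the segment
midpoint, temperature interpolated at the midpoint time, and the target
is the allocated intensity of the midpoint's cell (the source never
states how segment samples meet grid targets; midpoint-cell attachment
is the simplest consistent choice). Standardization is
$(X - \bar X)/\sigma$ with the sample ($n-1$) deviation. Aspect is
circular, so it is encoded as $(\sin D, \cos D)$ by default, with
`aspect = "raw"` reproducing the flat treatment of the source.

The network is one tanh hidden layer (default width 10, a common
toolbox default; the source does not state one) with a linear output,
trained by full-batch gradient descent with momentum 0.9 and early
stopping on validation MSE (patience 20 epochs, minimum improvement
$10^{-6}$). The original used a MATLAB toolbox whose default optimiser
is Levenberg–Marquardt; plain backpropagation was chosen for
dependency-free reproducibility — every fit is a deterministic function
of two seeds (weight init, split shuffle). Targets are standardized
internally and destandardized for reporting, so MSE is in g²/m⁴.

Samples split 70/15/15 into train/validation/test:
`round(n·0.70)` train, `round(n·0.15)` validation, remainder test — the
only rounding rule consistent with both the published 780 → 546/117/117
and the small-sample convention adopted here (10 → 7/2/1).

The determination coefficient is implemented exactly as published:
$$R^2 = 1 - \frac{\sum (W_i - W_{i1})^2}{\sum (W_i - W_{i2})^2},$$
with $W_i$ predicted, $W_{i1}$ actual and $W_{i2}$ the mean of the
*predicted* values. That denominator is nonstandard — the conventional
score centres the actuals — and the two diverge whenever the prediction
spread differs from the actual spread (predicted $(2,4,6)$ against
actual $(1,2,3)$: $-0.75$ versus $-6$). `r_squared_conventional()` is
provided; the screen reports the published form.

## The synthetic generator

No field data are deposited, so all end-to-end behaviour is exercised on
synthetic days that reproduce the *statistical structure* the pipeline
relies on: 06:00–18:00 days at 2-min fixes (361 per day); departure from
and return to a pen; a 15-min drinking dwell and a 60-min midday rest
dwell as 1 m jitter inside fixed polygons; grazing as a correlated
random walk (von Mises turning angles, $\kappa = 4$) whose proposed
steps are accepted by a Metropolis rule favouring higher NDVI
(acceptance $\min\{1, e^{\beta \Delta \text{NDVI}}\}$, $\beta = 6$); a
200-head flock with 15/70/15% in the <40, 40–60, >60 kg classes
(largest-remainder apportionment so counts always sum to the flock
size); NDVI built from synthetic NIR/red bands whose patch centres land
in [0.58, 0.90]; a smooth sinusoidal DEM; and a diurnal temperature
sinusoid peaking at 14:00, warmer in summer (mean 24 °C) than autumn
(10 °C). Each simulated day also plants ground truth: per-segment
constant-rate intakes summing exactly to the daily intake, and the
resulting intensity field on the 13-m grid.

Declared assumptions, not sourced facts: walking speeds (0.30 m/s
grazing, 0.90 m/s travelling — within the range reported for herded
sheep and giving a ~10 km daily path), patch geometry, dwell durations
and the movement model itself. The generator does not emulate GPS
positional error beyond dwell jitter, multi-animal interaction,
forage depletion feedback, or collar dropouts — so green tests show the
*pipeline arithmetic* is right under the stated structure, not that the
behavioural model matches real sheep. Seasonal contrast is generated
through the intake model (autumn forage is senesced, so the fresh-mass
fraction drops from 7.6% to 6.7% of body weight at a 0.45 dry-to-fresh
ratio), which makes summer totals exceed autumn totals as reported
qualitatively in the field.

## Numerical choices and degenerate inputs

- Rasters are row-1-north with half-open cells; grid origins snap down
  to a multiple of the cell size so cell indexing is reproducible.
- NDVI cells with zero denominator become nodata; negative NDVI (bare
  soil/water) is clamped to 0 with the count and pre-clamp minimum
  reported, honouring the stated [0, 1] range without losing evidence.
- Slope/aspect use Horn's 3×3 method (the GIS standard for 30 m
  products; the source names none) with edge replication; flat cells
  (gradient < $10^{-8}$) get nodata aspect. On an inclined plane the
  interior is exact (45°, 270° for a unit east-up slope); border cells
  are attenuated by replication, which tests acknowledge.
- Segments faster than 3 m/s are flagged as GPS glitches and removed
  with a count — sheep cannot sustain more between 2-min fixes.
- Kernel density truncates at $4h$; the brute-force oracle in the tests
  applies the same cutoff, and agreement is asserted at $10^{-9}$ on
  grids up to 50×50 with up to 200 fixes.
- Buffer weights are exact polygon-clip areas; the Monte-Carlo oracle
  (10⁵ points) agrees within 0.01.
- Screen tie-breaks: highest $R^2$, then lowest MSE, then lowest
  combination index.
- All randomness descends from one integer seed through a deterministic
  splitter (`derive_seed`), so reruns are byte-identical — the pipeline
  manifest asserts this with MD5 hashes.

## Problem sizes

The test suite runs synthetic days of 361 fixes, oracle comparisons at
up to 50×50 cells × 200 fixes, conservation over 100 random 40-segment
trajectories, and network fits at n = 400–780 with ≤ 2000 epochs; the
full suite completes in about a minute on one core. These sizes were
chosen as the smallest at which every contract is exercised at its
stated tolerance; nothing in the methods depends on them.

## Known limitations

- The published headline metrics ($R^2 = 0.97$, MSE = 0.73 g²/m⁴, field
  intensities 6.81–730.12 g/m²) derive from undeposited field data and
  are not reproducible here; the text's best-model MSE (0.73) and its
  Table value (0.0048) also disagree with each other. The package
  reproduces the *method*, with worked-example and recovery targets.
- Raster IO is ESRI ASCII grid only; no reprojection is performed —
  planar coordinates are local metres about a configurable lon/lat
  anchor (equirectangular), adequate at paddock scale (< 2 km).
- `literal_eq5` is faithful but non-conservative; totals from it should
  not be compared across days with different occupancy patterns.
- Zone rules are heuristics standing in for the original manual
  labelling; the override mechanism is the supported way to assert
  ground truth.
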