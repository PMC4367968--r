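---
title: "Quantifying compound-eye surface regularity with eyereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compound-eye surface regularity with eyereg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyereg)
```

## The problem

The Drosophila compound eye is a near-perfect hexagonal array of ommatidia.
Each ommatidial lens reflects incident light, so a reflected-light
photograph of a healthy eye shows a regular lattice of bright spots.
Retinal degeneration — for instance from eye-specific expression of a
polyglutamine-expanded human Ataxin-1 in SCA1 disease models — disrupts
this lattice and produces the qualitative "rough eye" phenotype.
Quantifying *how* rough an eye is, cheaply and reproducibly, is what this
package does: it converts a surface photograph into a single regularity
index, IREG, on a 0–1 scale where 1 is wild-type order and 0 is complete
degeneration. That turns qualitative genetic-modifier and drug screens
into a measurable dose–response readout, without histology.

## The pipeline

Each image passes through five stages:

1. **8-bit grayscale conversion** (`readEyeImage()`): RGB is collapsed
   with the BT.601 luminance weights; 16-bit data are rescaled linearly.
   All coordinates in the package are 0-based `(x = column, y = row)` with
   the origin at the top-left pixel.
2. **Rolling-ball background subtraction** (`subtractBackground()`): the
   background is the grayscale opening of the intensity surface by a ball
   of radius `rollingRadius` (default 50 px); subtracting it removes
   illumination trends while spots narrower than the ball survive. No
   pre-smoothing is applied.
3. **Inverted-shift averaging filter** (`surfaceFilter()`): the image is
   averaged with its intensity-inverted copy displaced horizontally by
   `displacement` pixels (default 1). Constant offsets map to uniform
   127.5, normalizing overall brightness differences between photographs.
   At displacement 1 the filter acts as a horizontal derivative: spot
   contrast is roughly halved and every maximum shifts by a uniform
   ~1.7 px along x. Because all downstream statistics are translation
   invariant, the shift is harmless; it only matters when comparing
   detected positions against ground truth, which the tests therefore do
   on the background-subtracted image.
4. **Prominence-filtered maxima detection** (`findMaxima()`): a local
   maximum is reported when its prominence — its height above the highest
   saddle connecting it to any higher summit — strictly exceeds the noise
   `tolerance`. Connectivity is 8-neighbour; equal-valued summit plateaus
   report one point at the plateau centroid (ties round away from zero);
   the global summit is measured against the image minimum, so a flat
   image yields nothing. Prominence is invariant to constant intensity
   offsets, and raising the tolerance can only remove maxima. The default
   tolerance of 10 is matched to the spot prominence that survives the
   displacement-1 filter; `calibrateDetection()` tunes `(tolerance,
   rollingRadius)` against a user's manual count by coordinate descent
   with a binary search on the tolerance coordinate (the detected count is
   monotone in tolerance), accepting within ±5% of the manual count.
5. **Feature extraction and scoring** (`makeGrid()`,
   `extractFeatures()`, `classProbabilities()`, `iregScore()`).

## The regularity variables

A square grid (cell side 50 px at the reference calibration of
1.85 µm/pixel, rescaled for other calibrations so a cell always covers the
same physical area, about 92.5 µm and several ommatidia across) is
anchored at the top-left of the ROI bounding box; only cells lying wholly
inside the ROI are kept. Eighteen variables summarize the maxima pattern:
four occupancy percentages (cells with fewer than 2/4/6/8 maxima);
mean/variance/skewness of maxima-per-cell plus the total count TOTMAX;
mean/variance/skewness across occupied cells of DIST, the distance from
the cell centroid to the center of mass of its maxima; across-cell
statistics of the within-cell skewness and kurtosis of point-to-centroid
distances; and LOGNNVAR, the natural log of the variance of
nearest-neighbor distances over the whole ROI.

Distances are expressed in *normalized units*: micrometres divided by the
1.85 µm reference pixel pitch, so images at any resolution feed the
classifier on the scale it was developed at. Variances use denominator
n−1; skewness and kurtosis are population standardized moments (kurtosis
non-excess); the skewness of a constant sample is defined as 0, while a
constant within-cell distance sample leaves skew/kurt undefined (`NA`,
excluded from aggregation). A perfectly regular lattice has zero
nearest-neighbor variance; LOGNNVAR is then floored at
`log(.Machine$double.eps)` and flagged.

The operational definition of the within-cell "skewness" and "kurtosis"
variables is ambiguous in their original description (the across-cell
structure conflicts with a legend describing intensity-value variance);
this package computes them on the within-cell point-to-centroid distance
distribution. None of these variables enters the final classifier, so the
choice cannot affect IREG; it is surfaced here for transparency.

## The classifier and IREG

Three variables carry the model: DISTM, DISTSKEW and LOGNNVAR. In a
regular eye, maxima fill each cell evenly (center of mass near the
centroid, DISTM small, with a right-tailed DIST distribution giving
positive DISTSKEW) and nearest-neighbor distances are nearly constant
(LOGNNVAR small). A five-class multinomial logistic model with the fully
degenerate class 4 as reference maps the triple to class probabilities

$$PP_i = \frac{e^{a_i}}{\sum_{j=0}^{3} e^{a_j} + 1},\qquad
  PP_4 = \frac{1}{\sum_{j=0}^{3} e^{a_j} + 1},$$

with linear predictors
$a_i = \text{independent}_i + \text{distm}_i\,\mathrm{DISTM} +
\text{distskew}_i\,\mathrm{DISTSKEW} + \text{lognnvar}_i\,\mathrm{LOGNNVAR}$.
The 16 built-in coefficients ship as a versioned JSON asset
(`builtinModel()`); the softmax is computed with max-subtraction so
extreme predictors cannot overflow. The regularity index is the ordinal
probability weighting

$$\mathrm{IREG} = \frac{4\,PP_0 + 3\,PP_1 + 2\,PP_2 + PP_3}{4} \in [0, 1].$$

Images yielding fewer than two maxima (or too few to occupy a grid cell)
cannot support the spatial statistics and are assigned complete
degeneration (IREG 0) — consistent with how a fully degenerated eye that
reflects no light should score.

## Rebuilding the model

The full training path is included so users can refit on their own
material: `pruneCorrelated()` (greedy elimination above |r| = 0.9; the
member of the worst pair with the larger mean absolute correlation is
dropped, ties broken by canonical variable order), `anovaScreen()`
(one-way ANOVA per variable from the textbook sum-of-squares formulas),
`pcaCluster()` (PCA on z-scored variables — the variables live on wildly
different scales, so correlation-matrix PCA is the defensible choice —
followed by 1-D k-means on PC1), `stepwiseSelect()` (forward entry at
p < 0.05 by likelihood-ratio test with a backward stay check at 0.10),
`fitMultinomial()` (Newton–Raphson with analytic Hessian, step-halving,
and explicit complete-separation detection) and `robustnessCheck()`
(refits across random train/test divisions and reports the across-split
spread of group-mean IREG).

Design choices made where the procedure was genuinely open:

* **PC1 clustering**: k-means with *deterministic quantile seeding*
  (initial centers at the evenly spaced quantiles of PC1, then Lloyd
  iterations) rather than randomized k-means++. The result is a pure
  function of the data — no RNG, no seed bookkeeping — with the same fixed
  points. Clusters are ordered along PC1 and oriented so class 0 sits at
  the regular end (lower DISTM, falling back to LOGNNVAR).
* **Stepwise thresholds** (0.05 entry / 0.10 stay) follow common
  SAS-style practice and are exposed as arguments. Note that with raw
  per-candidate entry tests, several noise candidates imply a
  non-negligible familywise false-entry rate (~18% with four candidates at
  0.05); the tests bound the false-entry rate rather than pretending the
  procedure is multiplicity-corrected.
* **Dunn post-hoc tests** (`compareGroups()`) are unadjusted by default,
  classic practice for the period; Bonferroni/Holm are available by
  argument. The Kruskal–Wallis omnibus uses the tie-corrected statistic.

## The synthetic world

`generateEyeImage()` renders a hexagonal lattice of Gaussian reflection
spots clipped to an elliptical "in focus" footprint, with spot dropout,
positional jitter, a linear illumination gradient and pixel noise, and
returns exact ground truth. Defaults describe a healthy eye at the
reference calibration: 256×256 px frame, 10 px pitch (18.5 µm, a
realistic ommatidial spacing), spot σ = 2 px, amplitude 180, gradient
span 30, noise σ = 4. Degeneration is emulated as jitter + dropout + spot
broadening, which reproduces the loss of reflection regularity without
modelling optics; bristles, glare and specular highlights are *not*
simulated, so a green synthetic test establishes correctness of the
measurement chain, not photographic realism. Every generator takes an
explicit seed and restores the caller's RNG state.

`simulateModelFeatures()` draws the three model features from a
five-group Gaussian mixture laid out along the degeneration gradient
(mirroring a five-genotype study design): DISTM means 3/5.5/6.8/7.5/9.5
(sd 1.2), DISTSKEW 1.5/0.9/0.5/0.1/−0.5 (sd 0.8), LOGNNVAR
−1.5/0/1/2/3.5 (sd 1.2), with labels sampled from the built-in model's
probabilities. The mixture was chosen for identifiability: the small
class-3 coefficients (0.242, −0.104) are not sign-identifiable at
n = 2000 from a single narrow Gaussian, whereas a design that populates
all class boundaries recovers all 16 coefficient signs within three
standard errors — which is exactly the parameter-recovery test the
training path is validated by.

## Numerical and degenerate-input conventions

* ROI polygons rasterize by the even-odd rule sampled at pixel centers
  `(x + 0.5, y + 0.5)`; a full-frame rectangle covers exactly
  width × height pixels.
* Image arithmetic is carried in floating point; quantization to 8 bits
  happens only on export.
* Plateau centroids round half-cases away from zero.
* Identical rows in the ANOVA screen give F = 0 (not 0/0); a zero
  within-group variance with distinct means gives F = ∞ and p = 0.
* `fitMultinomial()` flags complete separation (zero-deviance fits,
  diverging coefficients, or a singular Hessian) with a warning instead of
  returning silently diverged estimates.

## Limitations

The built-in coefficients are those of the published five-class model;
reproducing the original study's population-level numbers (explained
variance fractions, recovery percentages of specific modifiers) requires
the original 152-image dataset and is out of scope. Detection assumes
reflections are local intensity maxima: heavily saturated or defocused
photographs violate that and should be recalibrated with
`calibrateDetection()` on wild-type images. The synthetic generator's
regularity gradient is a model of degeneration, not a calibration of any
particular genotype.
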