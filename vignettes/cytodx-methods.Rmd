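---
title: "Nuclear morphometry and RBF case classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and RBF case classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cytodx)
```

`cytodx` turns manually delineated nucleus outlines on digitized thyroid
cytology slides into a per-patient benign/malignant call. This vignette
describes each model in the chain, the parameters that matter, the
numerical conventions, and what the synthetic validation data do and do
not establish.

## 1. Morphometry

A nucleus is a closed polygon in continuous pixel coordinates (0-based,
x rightward, y downward; the outline is implicitly closed). Validation
rejects outlines with fewer than three vertices, zero area, or
self-intersections.

**Geometric features.** Area and centroid come from the exact
signed-triangle (shoelace) decomposition, and the moments ellipse from
the exact polygon second-moment formulas, so none of the shape
descriptors depend on rasterization. Caliper (Feret) diameters are
projection widths over a uniform grid of 180 directions (1° steps) over
half a turn; the maximum is additionally bounded below by the largest
inter-vertex distance, which is the exact Feret maximum, so grid
resolution can only affect the minimum and mean. Radial statistics
resample the outline at 256 equal arc-length points and measure
distances to the area centroid; if the centroid falls outside a
strongly non-convex outline the result is still returned, flagged via
the `centroid_outside` attribute. Roundness is 4πA/P². The fractal
dimension is a box count on the outline rasterized at 4 subpixels per
pixel, with dyadic box sizes 1–64 and the dimension taken as the
negated least-squares slope of log N(s) against log s, clamped to
[1, 2]. Box counting is scale-sensitive by construction: the estimate
is meaningful when the box range lies inside the curve's scaling regime
(for smooth outlines, below the smallest feature separation; for
self-similar ones, above the generator segment). The validation
fixtures are sized accordingly.

**Densitometric features.** The mask is the set of pixels whose centers
fall inside the polygon, boundary-inclusive (an on-edge pixel center
counts as inside). Optical density uses BT.601 luminance
L = 0.299R + 0.587G + 0.114B and OD = −log₁₀((L+1)/(I₀+1)) with
I₀ = 255 by default, or the mean blank-field luminance when a blank
field is attached; the +1 offsets keep a zero pixel finite, and OD is
clipped at 0 from below. The stain/channel convention in the source
methodology is unstated; luminance with a configurable I₀ was chosen as
the neutral default. `sd_od` uses the population denominator N — the
pixel set is the full described population, not a sample. Margination
is the IOD fraction in the peripheral band of pixels within 10% of the
equivalent-circle radius of the outline (for a uniform disc this is the
outer-annulus area fraction, ≈0.19 at radius 20); heterogeneity is the
fraction of pixels with |OD − mean| > SD. When IOD = 0, margination is
defined as 0; when SD = 0, heterogeneity is 0. These three features
(margination, heterogeneity, fractal dimension) have no published
closed-form reference in this application area, so the definitions here
are the package's reference implementations, exercised against analytic
renders.

**Flat-field correction** divides out the illumination pattern:
corrected = raw × mean(blank)/blank per channel, rounded and clipped to
[0, 255]; blank pixels of 0 are treated as 1. Without a blank field the
image passes through unchanged with a warning.

## 2. The RBF nucleus classifier

The network is strictly three layers. Inputs are standardized (mean 0,
population SD 1; constant features are dropped with a warning). Hidden
units are Gaussian, φⱼ(x) = exp(−‖x − cⱼ‖²/2σⱼ²). The output is linear
with a bias, fit by ridge least squares against targets benign = 0,
malignant = 1, and the label is malignant when the score reaches the
decision cut (default 0.5; ties go to malignant — the conservative
direction in a cancer screen).

The literature this design follows describes clustering hidden nodes
and a data-adjusted hidden-layer size but no training algorithm, so the
classical RBF recipe was adopted:

* **Centers**: seeded k-means on the standardized training rows, 10
  restarts, up to 100 iterations. When k equals the number of rows,
  every point becomes a center (the exact-interpolation construction —
  with a small width scale and vanishing ridge, training scores
  reproduce the targets to numerical precision).
* **Widths**: σⱼ is the mean distance from cⱼ to its 2 nearest other
  centers (`width_neighbors = 2`); for k = 1, the mean distance of the
  points to the center. Non-finite or zero widths (possible with
  duplicated centers) are replaced by the mean positive width. A global
  `width_scale` multiplier (default 1) exists mainly for the
  interpolation limit.
* **Output weights**: (DᵀD + λI)w = Dᵀy with λ = 1e−6; on a singular
  system λ is escalated tenfold up to three times before failing.
* **Hidden-node count**: each k in `k_grid` (default 10, 20, 40, 80) is
  scored by balanced accuracy on an internal stratified 80/20 holdout
  of the training rows, and the winner is refit on all rows. Balanced
  accuracy is used because the cohort is class-imbalanced (≈64/36).

Determinism and order-invariance: all seeded steps operate on the
training rows in a canonical lexicographic sort order (features, then
label), so permuting the input rows changes nothing; identical data and
seed give an identical model. Model JSON serialization stores numbers
at 17 significant digits, which round-trips IEEE doubles exactly.

## 3. Case classification

For one patient, the tally is the count and percentage of structures
the network labeled benign. The numeric classifier calls the patient
benign when the count strictly exceeds the threshold; the percentages
classifier applies the same strict rule to the percentage. Strict
inequality means a case sitting exactly at the threshold is called
malignant, again the conservative direction.

Thresholds are optimized on training cases only. Every candidate on the
grid — counts 1..100 step 1, or percentages 1..100 step 0.1 (rounded to
one decimal to avoid floating-grid drift) — is evaluated for case-level
sensitivity and specificity (malignant positive), and the candidate
minimizing |Se − Sp| wins; ties break to higher overall accuracy, then
to the smaller threshold (which favors calling malignant at the
margin). The full sweep record is retained and is monotone by
construction: raising the threshold can only convert benign calls to
malignant, so sensitivity is non-decreasing and specificity
non-increasing along the grid. The numeric classifier uses an absolute
count even though slides carry different structure counts — that is the
method as defined; the percentages classifier is its normalized
counterpart, and on imbalanced slide sizes the two can genuinely
disagree.

## 4. Evaluation statistics

All indices come from raw counts, never from rounded percentages —
at cohort sizes in the hundreds, likelihood ratios computed from
2-decimal percentages visibly drift from the count-based values.
Zero-denominator proportions return NA and zero-denominator ratios +∞,
each with a warning, so perfect classifiers are representable.

The two-proportion z-test reports the difference in percentage points,
a 95% CI from the unpooled standard error, and a p-value from the
pooled standard error by default. Two reporting conventions seen in the
applied literature are supported explicitly: `variance = "unpooled"`
switches the test statistic to the unpooled SE, and `se_n` overrides
the SE denominators — some reports quote class-conditional rates (e.g.
sensitivity) while scaling uncertainty by the whole-split size; with
those settings the package reproduces such published intervals exactly.

ROC curves sweep the distinct score values (ties grouped into one
step), the AUC is trapezoidal — equal to Mann–Whitney concordance with
ties counted one half — and AUC confidence intervals and the paired
two-curve comparison use DeLong's method (via pROC), the standard
choice when the CI method is otherwise unspecified. A degenerate paired
comparison (identical scores) is reported as difference 0, p = 1. Case
scores for ROC construction are the negated benign count or percentage,
so larger means more malignant-looking.

## 5. The synthetic cohort

No per-nucleus dataset of this kind is publicly deposited, so the
generator emulates one at the cohort level:

* 447 cases, 64.4% benign (binomial per case), subtype labels drawn
  from the standard histological vocabulary with realistic weights —
  decorative metadata only.
* Structures per case: negative binomial, mean 92, dispersion (size) 8
  — moderate overdispersion around the ≈92 structures/slide scale;
  minimum 1. The default cohort totals ≈41,000 structures.
* Class mixing: a benign case contains 1% malignant-distributed
  structures; a malignant case 20% benign-distributed ones (tumor
  slides also carry follicular cells, histiocytes and colloid). The
  structure's latent class drives its feature draw but is observable
  only to the oracle; training labels are the case histology, exactly
  as for real slides, so the contamination acts as label noise.
* Features: 23-dimensional class-conditional Gaussian latents with
  unit SD, a 0.3 correlation among the nine size features, and a mean
  shift of 1.5 SD on area, IOD and OD-SD and 0.5 SD elsewhere, mapped
  through fixed monotone transforms onto plausible feature scales
  (positive sizes, ratios ≥ 1 recomputed from their axis draws,
  ordered min/mean/max tuples enforced by sorting). Monotone maps
  preserve the latent separation, so the planted signal is what the
  classifier can recover.

What this emulates: cohort composition, within-case mixing, realistic
per-case counts, and a nucleus-level signal strength that lands the
trained network near the 85–90% nucleus-level accuracy regime reported
for this methodology. What it does not emulate: real staining physics,
feature dependence beyond the single correlation block, slide
preparation artifacts, or inter-patient heterogeneity beyond the
binary class — so passing recovery tests demonstrates that the
pipeline's machinery is correct and leak-free, not that it would attain
any particular accuracy on clinical material.

Two planted-structure properties anchor the validation: with the
default effect sizes the full pipeline must recover case-level overall
accuracy ≥ 90% on held-out cases, and with the effect forced to 0 the
nucleus-level balanced accuracy on test data must sit at 50% (any
decision rule is uninformative then; raw accuracy would sit at the
class prior, which is why the no-leakage check uses the balanced form).

## 6. Validation scale and numerical conventions

The test suite validates morphometry against analytic renders and
brute-force oracles (1,000 random convex polygons for the Feret bound;
dense resampling and fine-grid rasterization for radii, moments and
area), the network against the exact-interpolation limit and a
two-Gaussian problem with a closed-form Bayes rule (within 3 points on
10,000 test draws), the threshold sweep against exhaustive re-scans,
and the statistics against simulation (5,000-rep type-I error for the
z-test, 200-instance Mann–Whitney equivalence for the AUC, 100-rep
DeLong CI coverage). End-to-end checks run the full default-scale
cohort (447 cases, ≈41,000 structures). These sizes were chosen so the
whole suite exercises study-scale data while remaining comfortably
runnable on a laptop.

Degenerate-input conventions, collected: empty case → error (inadequate
specimen); polygon smaller than one pixel → error; boundary outside the
image → per-structure skip in batch extraction, error in single
extraction; absent blank field → identity with warning; single-class
truth → error everywhere a comparison needs both classes.

## 7. Known limitations

* Nucleus delineation is assumed given; there is no segmentation and no
  GUI (automated identification is the natural next step for this
  methodology, not part of it).
* The RBF training recipe is a reconstruction — the original
  hyperparameters are unpublished, so nucleus-level results of the
  source study are validated through its printed confusion matrices,
  not regenerated from raw data.
* Published case thresholds (37 nuclei, 51%) arise from the original,
  undeposited cohort; on synthetic cohorts the optimizer finds the
  analogous balanced thresholds for its own data, and the printed
  values serve only as documentation constants.
* No stain-specific spectral unmixing; OD is luminance-based.
* No multi-class prediction: diagnostic subtype labels exist in the
  data model but only the benign/malignant axis is classified.
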