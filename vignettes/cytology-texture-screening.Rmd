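---
title: "Texture-based screening of oral cytology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based screening of oral cytology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotexture)
```

## The screening problem

Exfoliative cytology collects shed epithelial cells from a suspect oral
lesion with a brush, stains them (Papanicolaou), and asks whether the smear
contains dysplastic cells. Dysplasia disturbs chromatin organisation and
nuclear morphology, and under the microscope this reads as *texture*: a
dysplastic cell's intensity surface is more disordered, with stronger local
variation, than a normal cell's. `cytotexture` quantifies that with
gray-level co-occurrence matrix (GLCM) statistics and turns the five-feature
profile into a single screening score per subject.

The pipeline is: contrast enhancement → fuzzy c-means (FCM) segmentation →
masked GLCM features per cropped image → per-subject aggregation →
two-group statistics → composite score → ROC evaluation. Each stage is an
exported function; `run_pipeline()` chains them under one seed.

## Preprocessing

Images load as 8-bit grayscale (`load_image()`); RGB inputs are reduced with
the Rec.601 luminance weights (0.299, 0.587, 0.114), and other stored bit
depths are rescaled to 8-bit by multiplying the decoder's unit-scale values
by 255 and rounding. The default enhancement is a linear percentile stretch
(2nd–98th percentile onto the full range). It was chosen over histogram
equalisation as the default because it is monotone — it cannot reorder pixel
intensities, so it cannot invert any co-occurrence relationship — and has
only two transparent parameters; equalisation remains available
(`enhance_contrast(..., "equalize")`). Constant images are returned
unchanged with a warning rather than dividing by zero.

Regions of interest use a 0-based, half-open `(row, col)` convention
throughout (`roi_rect()`, `crop_roi()`); out-of-bounds ROIs are an error,
never clamped, so coordinate mistakes surface instead of silently shifting
the analysed field. The pipeline's default order is crop-then-enhance, so
the stretch adapts to the marked field rather than to the whole slide; both
orders are available by calling the two functions directly.

## Fuzzy c-means segmentation

Stained cellular material is darker than the background, so segmentation
reduces to clustering pixel intensities. FCM minimises
$J_m=\sum_i\sum_k u_{ik}^m (x_k-v_i)^2$ by alternating the standard
membership and centre updates; the objective, evaluated after each full
iteration, is non-increasing by construction of the alternating
minimisation, and the per-pixel memberships sum to one — both are asserted
in the test suite on every run. Numerical choices:

* **Fuzzifier** `m = 2`, the near-universal convention.
* **Clusters** `c = 2` (cell material vs background) by default; `c = 3`
  separates background / cytoplasm / nucleus.
* **Initialisation** at evenly spaced intensity quantiles — deterministic,
  so segmentation is reproducible with no seed at all; random initialisation
  is available with a seed.
* **Convergence**: maximum centre shift below `1e-5`, capped at 300
  iterations.
* **Singularity rule**: a pixel exactly at a centre takes membership 1
  there (split evenly if it coincides with several).
* A constant image (fewer distinct values than clusters) is refused
  explicitly rather than returning a meaningless partition.

Internally `segment_image()` clusters the distinct 8-bit intensity levels
weighted by their pixel counts, which is algebraically identical to
clustering every pixel (memberships depend only on a pixel's value and the
centres) and much faster; a test verifies the equivalence.

## GLCM features

The image is quantized into `n_levels` equal-width bins and the
co-occurrence matrix $p(i,j)$ is accumulated over ordered pixel pairs at a
fixed displacement, optionally restricted to pairs lying wholly inside the
segmentation mask. Feature definitions follow the conventions of the
classical MATLAB texture functions — contrast with the squared level
difference, homogeneity with the $1+|i-j|$ denominator, energy as the sum
of squared probabilities, entropy in bits with $0\log 0 \equiv 0$, and
correlation from the marginal means and SDs of the row/column indices,
returned as an explicit undefined flag when a marginal variance is zero.
This convention choice is the single most consequential one in the package,
since published feature values are only comparable under the same formulas.

Defaults: `n_levels = 8`, a single offset `(0, 1)`, asymmetric counting —
again the classical defaults. All of it is configurable, and the pipeline
records the configuration in a JSON sidecar next to the features CSV. One
deliberate deviation from "auto" min/max scaling: `image_features()` bins
over the full 8-bit range `(0, 255)` by default rather than each image's
own range, so that the amplitude of intensity fluctuations is part of the
signal instead of being normalised away per image. Color input is handled
as Rec.601 luminance; a first-order histogram entropy
(`histogram_entropy()`) is reported alongside the co-occurrence entropy in
pipeline output, since published "entropy" values in this literature are
occasionally of that kind.

Correctness of the counting core rests on an independent oracle: the test
suite compares `compute_glcm()` elementwise (tolerance 1e-12) against a
deliberately naive double-loop pair counter across random small images,
four offsets, masked and unmasked, symmetric and asymmetric.

## Group statistics

The unit of analysis is the *subject*: the study design this package
follows images about ten cropped fields per smear, and group sizes refer to
subjects, so image-level features are averaged per subject before testing
(image-level mode is retained for sensitivity analysis). Group comparison
uses the unpaired t-test computed from group summaries; both the pooled
(Student) and Welch variants are implemented, with pooled as the default —
at equal group sizes the two statistics coincide to machine precision,
which is also tested. Five features are tested at $\alpha = 0.05$ with no
multiplicity correction by default, matching practice in this screening
literature; a Bonferroni option exists.

A reproducibility caveat that the package states explicitly
(`screening_benchmarks()`): of the five published t-values this design is
associated with, only the entropy row (9.68) is recoverable from the
published two-decimal group means and SDs at n = 80 per group; the other
four are not, presumably because the published summaries are rounded. The
package therefore treats the entropy row as the only summary-level anchor
and flags the rest as non-recoverable rather than silently reconciling
them.

## The composite scoring index

No closed formula is published for the original scoring index; this package
adopts a ratio of reference-normalised features,
$\big[(E/E_0)(C/C_0)\big] / \big[(G/G_0)(R/R_0)(H/H_0)\big]$, for three
reasons: it mirrors the ratio construction of oxidative-stress-index-style
composite markers from which the idea derives; it respects the known
directions of change (numerator features rise in dysplasia, denominator
features fall); and it reproduces the threshold-1 semantics — the reference
$E_0,\dots,H_0$ is the control-group mean vector, so an average control
subject scores exactly 1. The decision rule is strict (`score > 1` →
malignant; a tie is called normal). Alternative index definitions can be
evaluated by scoring manually and passing the scores to `roc_analysis()`.

Two properties worth knowing: the score is invariant to jointly rescaling
any feature and its reference (units cancel), and because the reference
centres controls *at* 1, roughly half of the controls land above the
screening threshold when within-group spread is tight — threshold 1 is a
screening rule inherited from the index's construction, not the ROC-optimal
operating point. The ROC curve itself (all distinct score thresholds,
trapezoid AUC) is the measure of separation.

## The synthetic-data generator

No clinical image set is publicly available for this design, so the
generator is a first-class module, not a fixture. It emulates two things:

1. **Images** (`generate_cell_image()`, `generate_cohort()`): elliptical
   cells with random centre, semi-axes and orientation on a bright
   background (8-bit grayscale PNG, default 256×256 — the published design
   states no pixel dimensions, so this is a free choice), with a darker
   concentric nucleus and an intra-cell texture of smoothed Gaussian noise.
   The class presets differ in texture correlation length (`control` 6 px
   vs `oscc` 3 px), fluctuation amplitude (0.06 vs 0.10), nuclear
   darkening (0.22 vs 0.30, hyperchromatism) and cell-size spread
   (pleomorphism). Smoothed-noise texture was chosen because its two
   parameters give monotone, interpretable control over all five GLCM
   features; the preset values were calibrated once, fixed here, and are
   verified by a direction-of-effect test over 50 images per class. The
   ground-truth mask of rendered cell pixels is returned with every image.
2. **Feature tables** (`generate_feature_table()`): per-subject
   five-feature Gaussian draws at the group means and SDs characteristic
   of published GLCM cytometry of oral smears (OSCC-like entropy
   2.05 ± 0.19 vs control 1.84 ± 0.04, and so on), 80 subjects per group.
   Each group's stream is keyed to the *group label*, so swapping the two
   specifications swaps the generated groups exactly.

Seed policy: one master seed; per-subject and per-image seeds are derived
by a fixed integer mix (`derive_seed()`), so cohorts are bit-reproducible
and subjects independent. Cells that would leave the canvas are clipped and
counted, never dropped silently; heavy overlap is limited by rejection
sampling but not forbidden.

What the generator does **not** emulate: PAP-stain colour, overlapping and
folded cell clusters (excluded from the original analysis protocol),
hemorrhage and staining artifacts, or optics (defocus, vignetting,
chromatic noise). Passing tests on synthetic cohorts therefore demonstrate
that the *pipeline machinery* is correct and that the feature shifts follow
from the modelled texture differences — they do not certify clinical
accuracy on real smears, and the published clinical operating point
(accuracy 88%, sensitivity 91%, specificity 81%) is explicitly not a
quantity this package claims to reproduce
(`screening_benchmarks()$operating_point$reproducible` is `FALSE`).

## Problem sizes and reproducibility

The test suite runs the full pipeline end to end on a scaled-down smoke
cohort (8 + 8 subjects × 10 images at 128×128), where all five features
already separate decisively and the composite AUC exceeds 0.9; the
default-size cohort (80 + 80 × 10 at 256×256, 1600 images) runs in a few
minutes via `run_pipeline(list(seed = 1L), "out")`. The acceptance script
(`scripts/acceptance.R`) recomputes the mean entropy t-statistic over 500
simulated 80 + 80 cohorts. Every random quantity anywhere in the package is
a pure function of the supplied seed, and `run_pipeline()` writes no
timestamps, so identical configurations produce bit-identical output
directories.

## Known limitations

* Intensity-only segmentation: touching cells are not split (no watershed),
  matching the original protocol's exclusion of overlapped cells.
* Image-within-subject correlation is handled by averaging, not by a
  mixed-effects model.
* The scoring index is a documented reconstruction; other composites (or a
  trained classifier, deliberately out of scope) may behave differently.
* GLCM parameters (levels, offsets, symmetry) of the original analysis are
  unreported; the defaults here are declared assumptions, surfaced in the
  output metadata.
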