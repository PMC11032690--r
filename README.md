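# cytotexture

Texture-based screening of oral exfoliative cytology images.

Early oral squamous cell carcinoma (OSCC) is usually screened by a
cytopathologist reading PAP-stained smears cell by cell — slow, skilled work
that is easy to automate badly. A well-studied alternative quantifies the
*texture* of the stained cells: dysplastic cells are more disordered and less
locally uniform than normal epithelium, and this shows up in the gray-level
co-occurrence matrix (GLCM) of the image. `cytotexture` implements the whole
screening pipeline for this approach, plus a calibrated synthetic cytology
image generator so that every stage can be exercised and tested without
clinical images.

## The model at the core

For a quantized image, the GLCM at displacement $(\delta r, \delta c)$ is the
joint distribution $p(i,j)$ of gray levels at pixel pairs separated by that
offset. Five classical statistics summarise it:

- entropy $-\sum_{i,j} p \log_2 p$ and contrast $\sum_{i,j}(i-j)^2 p$, which
  **rise** in dysplastic cells;
- energy $\sum_{i,j} p^2$, correlation
  $\sum_{i,j}(i-\mu_i)(j-\mu_j)p/(\sigma_i\sigma_j)$ and homogeneity
  $\sum_{i,j} p/(1+|i-j|)$, which **fall**.

The pipeline: percentile contrast stretch → fuzzy c-means segmentation of
cells from background (minimising
$J_m=\sum_{i,k} u_{ik}^m (x_k - v_i)^2$) → masked GLCM features → per-subject
averaging over cropped fields → unpaired t-tests between groups → a composite
scoring index

$$\mathrm{score} \;=\; \frac{(E/E_0)\,(C/C_0)}{(G/G_0)\,(R/R_0)\,(H/H_0)}$$

where $E_0,\dots,H_0$ are the control-group means: the numerator collects the
features elevated in dysplasia, the denominator those reduced, so the score
exceeds 1 exactly when the profile shifts in the malignant direction. Calls
(`score > 1` → malignant) are evaluated with ROC analysis.

## Worked example

```r
library(cytotexture)

# one synthetic dysplastic-class image, segmented and featurised
out  <- generate_cell_image(class_preset("oscc"), size = c(128, 128), seed = 1)
mask <- segment_image(out$image)
image_features(out$image, mask = mask)
#>    entropy  contrast    energy correlation homogeneity
#> 1 2.694742 0.1778397 0.2227554    0.895598   0.9153936
dice_overlap(mask, out$mask)
#> [1] 0.993

# a small end-to-end cohort: 8 + 8 subjects, 10 images each
res <- run_pipeline(list(seed = 42L,
                         synth = list(n_per_group = 8L,
                                      images_per_subject = 10L,
                                      size = c(128L, 128L))),
                    "demo_run")
res$report[, c("feature", "mean_oscc", "mean_control", "t", "p")]
#>       feature mean_oscc mean_control     t        p
#> 1     entropy     3.177        2.358  58.7 3.75e-18
#> 2    contrast     0.251        0.109 102.8 1.50e-21
#> 3      energy     0.148        0.254 -45.3 1.39e-16
#> 4 correlation     0.909        0.933 -18.4 3.21e-11
#> 5 homogeneity     0.892        0.954 -95.3 4.30e-21
res$roc
#> <roc_result> AUC 1.000 (8 pos / 8 neg); at threshold 1: accuracy 87.5%,
#> sensitivity 100.0%, specificity 75.0%
```

All five features shift in the direction expected for dysplastic smears
(entropy and contrast up, the rest down), every t-test is decisive, and the
composite score separates the classes completely (AUC 1.0). At the fixed
screening threshold of 1 some controls are still called positive, because the
reference calibration centres the *average* control at a score of 1 — the
threshold is a screening rule, not the ROC-optimal cut.

Group statistics work directly from published-style summaries too:

```r
unpaired_t(2.05, 0.19, 80, 1.84, 0.04, 80)
#> t = 9.67, df = 158, p = 1.1e-17
```

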