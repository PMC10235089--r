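---
title: "Contextual TIL phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual TIL phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open.

## 1. The contextual feature model

Each TIL is described by the cellular context around its centroid rather
than by its own morphology alone. Three **nested closed discs** of radius
`dL * c(10, 20, 30)` pixels are drawn around the TIL, with `dL = 20` px
the average lymphocyte diameter at 20x magnification (0.5 um/px), so the
scales are 200, 400 and 600 px, i.e. 100--300 um — from the immediate
niche up to a neighborhood spanning a few hundred cells. Discs are
cumulative, not annular: the published description of "incremental
increasing radii" reads most naturally as nested, and nested discs make
the count features monotone across scales, a property the tests pin down.
The index cell is always excluded; membership uses the closed boundary
(distance $\le r$).

Per disc, 96 descriptors in five families are computed over the TIL and
non-TIL neighbor groups separately:

| family | count | content |
|---|---|---|
| A density | 6 | TIL/non-TIL/total counts, TIL fraction, TIL and non-TIL per mm² |
| B distance | 8 | centroid distance to {TIL, non-TIL} × {mean, sd, min, max} |
| C morphology | 40 | {area, perimeter, eccentricity, equivalent diameter, solidity} × {mean, sd, min, max} × {TIL, non-TIL} |
| D color | 18 | per-nucleus mean {R, G, B} × {mean, sd, max} × {TIL, non-TIL} |
| E texture | 24 | 12 co-occurrence statistics, averaged over {TIL, non-TIL} neighbors |

Three radii × 96 give the 288-dimensional vector. The itemized catalog is
a **reconstruction**: the published main text names the families and the
total of 288 but not the item list, so the partition above was chosen to
satisfy both constraints exactly and is frozen in `feature_catalog()`,
whose ordering is part of the package contract.

**Empty-group convention.** A TIL with no neighbors of a group in a disc
gets 0 for every statistic of that group, including the TIL fraction.
Zero is monotone with "no signal" and, crucially, keeps NaN out of the
downstream mixture model; the fill is applied *before* standardization.

**Texture.** The 12 co-occurrence statistics (angular second moment,
contrast, correlation, sum-of-squares variance, inverse difference
moment, sum average, sum variance, sum entropy, entropy, difference
variance, difference entropy, information measure of correlation 1) are
computed per nucleus on the 8-bit grayscale bounding-box patch, at
distance 1 with a symmetric matrix, 32 gray levels, averaged over the
four standard directions. These are standard conventions; the source
description is silent on them. Degenerate patches follow a fixed rule
(constant patch: ASM = IDM = 1, everything entropy- or spread-like 0;
undefined correlation reported as 0).

## 2. The mixture model of immune niches

TIL vectors are z-scored with statistics fit on the training table
(zero-variance features are dropped and recorded; assignment of new data
reuses the training statistics, so re-assigning the training set
reproduces its labels). The niche model is a K-component Gaussian
mixture fit by EM with:

* **diagonal covariances, variance floor 1e-6** — at 288 dimensions a
  full covariance per component is ill-conditioned at realistic TIL
  counts (tens of thousands of cells), and the floor prevents collapse
  onto single points;
* **k-means++ seeding, 5 restarts, one controlling seed** — EM is
  multimodal; restarts with the best log-likelihood kept make the fit
  reproducible and reasonably insensitive to initialization;
* **bounded iterations (200) with relative tolerance 1e-8** —
  non-convergence is flagged, never silently accepted.

`K = 8` is adopted as the published configuration and enforced in
paper mode; `select_k()` provides a BIC sweep as a non-normative helper
because the original selection procedure is not reproducible from the
main text. Hard assignment is the argmax posterior responsibility with
ties broken toward the lowest cluster index.

## 3. The risk model

Patient *i* is the vector `N_i` of TIL counts per cluster, pooled over
tiles. **Raw counts** are used, following the risk-score formula's
wording ("number of clusters"); a proportion mode is available as an
option because total TIL burden otherwise enters the score. The score is
`OSRS_i = sum_j N_ij beta_j` with no intercept.

`beta` comes from an elastic-net-penalized Cox partial likelihood
(glmnet). The mixing weight defaults to α = 0.5 — the published text
names the method but not its hyperparameters, and an even ridge/lasso
mix is the conventional neutral choice — with penalty strength by 5-fold
cross-validated partial likelihood on seeded folds. Ties use the
package default (Breslow within the penalized fit; Efron in the
unpenalized evaluation fit, the `survival` default). Zero-variance count
columns are retained with their coefficient forced to 0, with a warning,
so the coefficient vector always has length K.

The stratification cutoff is the median training OSRS. Equality at the
cutoff is open in the published wording ("higher than" / "lower than");
the package fixes **score > cutoff ⇒ high risk**, so an all-tied cohort
is uniformly low risk. Cluster roles are the sign of the coefficient
(positive constructive, negative obstructive, exactly zero neutral).
Note the published worked example itself contains an internal
inconsistency for the squamous model (the text names one cluster
obstructive whose printed coefficient is positive); the sign rule is
treated as normative.

Evaluation reports the two-sided Mantel--Haenszel log-rank test, the
hazard ratio (high vs low) with 95% CI from a univariable Cox fit,
Harrell's C over the continuous scores with the standard error of the
`survival::concordance` estimator, and Kaplan--Meier product-limit
curves. Monotone-separated groups (infinite-coefficient warnings from
the partial likelihood) report the finite iterate.

## 4. Segmentation and TIL classification

Tiles are stain-normalized by the Macenko procedure: optical densities of
tissue pixels (OD above 0.15) are projected onto their top-two principal
plane, the robust 1st/99th-percentile angle extremes become the stain
vectors, and per-pixel concentrations are rescaled to a reference
profile's 99th-percentile concentrations. Tiles with under 1% tissue
pixels raise an error rather than producing garbage stain vectors. Since
only two stains are reconstructed, residual color off the H&E plane is
discarded — exact self-reconstruction holds only for true two-stain
images, which is what the tests use.

Nuclei segmentation deconvolves the hematoxylin channel against the
standard H&E basis, smooths (Gaussian, sigma 1 px), thresholds
foreground against the background level (median + 3 robust SDs, with an
absolute concentration floor of 0.3), and splits touching nuclei by a
distance-transform watershed (tolerance 0.5). The background-based
threshold was chosen over Otsu deliberately: infiltrated tiles have
*three* intensity modes (background, pale epithelial nuclei, dark
lymphocytes) and Otsu tends to bisect the upper two, dropping every pale
nucleus. Objects under 16 px² (sub-lymphocyte debris at 20x) are removed.
Solidity uses the lattice-point count of the pixel convex hull (Pick's
theorem), which makes it exactly 1 for convex pixel regions. An ingest
path accepts externally produced masks and class labels, since the
original deep-learned segmenters are external tools.

Rule-mode TIL classification thresholds area (≤ 450 px²), mean grayscale
intensity (≤ 0.52) and solidity (≥ 0.8) — small, dark, compact nuclei.
The thresholds are calibrated to the renderer's palette and are exposed
as parameters; for real slides the SVM mode (`fit_til_classifier()`)
trained on labeled records is the appropriate route.

## 5. The synthetic-data generator

The generator defines the study conditions for every test:

* **Spatial structure.** TILs follow a Thomas cluster process (hotspot
  parents, Poisson offspring, Gaussian dispersion 60 px ≈ 30 um by
  default) over a homogeneous Poisson carpet of non-TIL nuclei
  (1500/mm², a typical nuclear density for tumor tissue at 20x).
  Overlap is resolved by rejection sampling with minimum centroid
  separation 0.8·(r1+r2), bounded at 50 retries per cell, which keeps
  rendered tiles watershed-solvable; exhausting the bound is a
  degenerate-configuration error, not a silent fix.
* **Phenotypes.** Eight planted phenotypes share a lymphocyte-like base
  profile and differ by fixed offsets on eight signature descriptors;
  `phenotype_separation` scales the offsets (1 = realistically
  overlapping, 3 = clearly separated for recovery experiments).
* **Subtypes.** Hotspot-level phenotypes carry CD4/CD8/CD20 mixes whose
  first, fourth and sixth rows follow the reported niche compositions
  (a CD8-dominated, a balanced, and a CD8-rich/B-cell niche); the rest
  are plausible completions.
* **Survival.** Event times are exponential with log-hazard
  `z(N) · beta_star` over column-standardized counts — memoryless by
  design so closed-form checks exist — and censoring is an independent
  exponential clock calibrated to the requested censoring fraction. The
  default planted effect alternates ±1.25 per standard deviation of a
  count column (hazard ratio ≈ 3.5 per SD), a deliberately strong
  effect: recovery experiments ask whether the machinery finds a signal
  that is genuinely there, not whether it can milk a marginal one.
* **IF stacks.** Each TIL's membrane ring is painted in its subtype's
  channel; contested membrane pixels belong to the nearest TIL (and the
  quantifier applies the same ownership rule), so noise-free calls are
  correct by construction. The distortion model is piecewise-linear over
  control points — the same family the registration module fits — so
  recovery is exact in the noise-free limit.
* **Expression.** Planted genes are `r·z + sqrt(1-r²)·noise` against a
  chosen cluster's standardized counts, calibrating the population
  Pearson correlation to `effect_r`; background genes are independent.

What the generator does **not** emulate: stromal/tumor architecture
beyond point processes, staining artifacts, scanner variation,
out-of-focus regions, nuclear texture that differs inside vs outside the
niche, or cohort-level confounding (stage, treatment). Passing tests
therefore demonstrate the correctness and sensitivity of the machinery
under controlled conditions, not clinical performance; the published
cohort-level hazard ratios and C-indices rest on protected patient data
and are out of reach of any desk-scale simulation.

## 6. Registration and subtype pairing

Control-point registration triangulates the source points (Delaunay, via
deldir) and fits one exact affine map per triangle, so the transform is
exact at control points and piecewise-linear in between; querying outside
the hull extends by the nearest triangle and flags the point. At least 4
non-collinear, duplicate-free pairs are required. The membrane is the
morphological dilation of the (transformed) nucleus by `ring_width = 2`
px (~1 um at 20x, a membrane-scale default the source leaves
undimensioned), minus the nucleus, with contested pixels assigned to the
nearest TIL; per-marker means are divided by the per-core AQUA scalars
(inputs, as in the source) and the argmax marker is the label. Exact
ties are left unassigned rather than resolved by a priority order, which
would bias one marker systematically.

## 7. Gene association

Pearson correlations are computed gene-wise against cluster counts and
optionally the OSRS (both exposed, since the published phrasing uses
both). "50% of the maximum correlation" is read as **maximum absolute
correlation** — the source reports both positively and negatively
correlated pathways, so a signed maximum would discard half the signal —
with the sign retained in reports. Enrichment is the one-sided
hypergeometric over-representation test against user-supplied GMT gene
sets intersected with the universe, with Benjamini--Hochberg adjustment;
live ontology queries are replaced by versioned GMT files for
determinism.

## 8. Problem sizes and reproducibility

The test-suite and acceptance-script problem sizes were chosen so that
each statistical check has clear resolution while the whole suite stays
comfortably interactive: 200-cell maps (20 of them) for feature-oracle
equivalence, 20,000 × 288 for the 8-component fit, 900 × 288 for mixture
recovery, cohorts of n = 300 over 20 replicate seeds for coefficient-sign
recovery and risk separation, 1000 genes × 400 patients for the
activation-gene rule, and 512 px tiles for rendering/segmentation
round-trips. All randomness flows from explicit seeds; the pipeline
manifest records per-stage seeds and artifact hashes, and re-running an
identical configuration reproduces identical hashes.

## 9. Known limitations

* The 96-per-radius catalog and the 16-item completion of the denTIL
  family are documented reconstructions of lists that were never
  published in full; counts and the named items are pinned by tests.
* spaTIL is a deliberately reduced family (10 features); the full
  several-hundred-item catalog belongs to prior published work.
* The watershed stage stands alone; the original pipeline combined it
  with a deep segmenter whose combination rule is unpublished.
* Rule-mode TIL classification is calibrated to the synthetic renderer;
  real H&E requires the trained-classifier route.
* The mixture model's diagonal covariance cannot represent correlated
  feature noise within a niche; with 288 standardized features this is a
  bias/variance trade-off, not a statement about the data.
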