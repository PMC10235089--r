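# phenotil

Contextual phenotyping of tumor-infiltrating lymphocytes (TILs) on
H&E-stained histology, and conversion of a patient's immune-niche
composition into an overall-survival risk score.

## The problem and who this is for

On routine H&E slides, TILs are usually counted as one homogeneous
population, yet activated, exhausted and bystander lymphocytes contribute
very differently to outcome. This package is for computational-pathology
researchers who want to characterize *each* TIL by the company it keeps —
the density, morphology, color and texture of its neighboring cells at
several length scales — and to test whether the resulting immune-niche
composition stratifies patient survival.

## The method

For every TIL with centroid **c**, three nested closed discs of radius
`dL·10`, `dL·20` and `dL·30` pixels are drawn (`dL = 20` px, the average
lymphocyte diameter at 20×, so 200/400/600 px ≙ 100/200/300 µm). Within
each disc, 96 descriptors of the neighboring TILs and non-TILs are
computed in five families — density (6), centroid distances (8),
morphology (40), color (18) and gray-level co-occurrence texture (24) —
giving the full ordered vector of **288 contextual features** per TIL.

TIL feature vectors are z-scored and clustered with a Gaussian mixture
model (diagonal covariances, EM with k-means++ restarts); the paper-mode
configuration uses **K = 8** immune-niche clusters. Patient *i* is then
the count vector `N_i ∈ ℕ⁸` of its TILs per cluster, and the
overall-survival risk score is the linear combination

```
OSRS_i = Σ_j N_ij β_j
```

with `β` the coefficients of an elastic-net–regularized Cox
proportional-hazards fit (mixing weight α = 0.5, penalty by 5-fold
cross-validated partial likelihood). Patients above the training-median
OSRS are called high risk; separation is evaluated by the Mantel–Haenszel
log-rank test, the hazard ratio of a univariable Cox fit, Harrell's
C-index and Kaplan–Meier curves. A cluster with `β_j > 0` is labeled
*constructive*, `β_j < 0` *obstructive*.

Around this core the package provides:

* watershed-based nuclei segmentation with Macenko stain normalization
  and rule- or SVM-based TIL classification (`segment_nuclei()`,
  `macenko_normalize()`, `classify_tils()`);
* the denTIL comparator family (19 tile-level TIL-density features) and a
  reduced spaTIL spatial-architecture family, with the shared
  mean/median/skewness/kurtosis patient aggregation;
* piecewise-linear (control-point) H&E↔IF co-registration and
  membrane-based CD4/CD8/CD20 subtype calling with AQUA normalization
  (`fit_registration()`, `quantify_subtype()`);
* gene-expression association: Pearson correlation against cluster
  counts/OSRS, the 50%-of-max activation-gene rule, and hypergeometric
  gene-set enrichment with Benjamini–Hochberg FDR (`enrich()`);
* a synthetic tissue simulator (clustered TIL point patterns, rendered
  H&E-like tiles, planted survival effects, co-registered IF stacks,
  expression matrices) so the full pipeline runs without external data.

## Worked example

Simulate a tile, extract contextual features, then fit and evaluate a
risk model on a simulated 200-patient cohort with a planted ±1.25
log-hazard effect:

```r
library(phenotil)

cfg <- sim_config(tile_size = 512L, n_til_hotspots = 4L, til_per_hotspot = 15,
                  lambda_nontil = 600, hotspot_dispersion = 50,
                  phenotype_separation = 3)
g <- gen_cell_map(cfg, seed = 1)
g$cell_map
#> <cell_map> tile 'sim-seed1' (512 x 512 px, 0.5 um/px): 111 cells (63 TIL, 48 nonTIL)

feats <- extract_all(g$cell_map)
dim(feats)
#> [1]  63 289           # 63 TILs x (til_id + 288 features)

N    <- gen_cluster_counts(200, seed = 2)
surv <- gen_survival(N, rep_len(c(1.25, -1.25), 8), censor_rate = 0.2, seed = 3)
fit  <- fit_risk_model(N, surv, seed = 4)
fit
#> <risk_model> elastic-net Cox (alpha 0.50, lambda 0.01512), n = 200 (124 events)
#>      C1      C2      C3      C4      C5      C6      C7      C8
#>  0.1069 -0.1204  0.0893 -0.1858  0.0754 -0.2371  0.1132 -0.1006
#> cutoff (training median OSRS): -0.5673

scores <- compute_osrs(N, fit)
evaluate_survival(surv, stratify(scores, fit), scores)
#> <eval_report> log-rank p = 7.76e-42; HR (high vs low) = 19.5 (95% CI 11.7-32.7);
#>               C-index = 0.921 (SE 0.010)
```

The fitted coefficients alternate in sign exactly as planted: `tidy(fit)`
labels C1/C3/C5/C7 constructive and C2/C4/C6/C8 obstructive. The high-risk
group (OSRS above the training median) dies markedly faster — the hazard
ratio of 19.5 and C-index of 0.92 reflect the strength of the planted
effect, not a claim about clinical data. `autoplot(report)` draws the
Kaplan–Meier curves and `autoplot(fit)` the coefficient lollipop plot.

A command-line front end with `demo`, `simulate`, `features`, `cluster`,
`risk` and `evaluate` subcommands is installed at `inst/cli/phenotil`.

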