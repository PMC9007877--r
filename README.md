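# nucmorph

Quantitative histomorphometric analysis (QHA) of tumor nuclei in histology
image patches, built around the finding that computer-extracted nuclear
features — size, shape, co-occurrence texture, orientation disorder, and
the spatial organization of cell graphs — distinguish stage II from stage
IV colon cancer and stratify survival. The package is for computational
pathology researchers who have (or want to simulate) segmented nuclei in
image patches and need a tested, reproducible pipeline from label masks to
patient-level classification and survival analysis.

## What it computes

For every patch (image + integer label mask) the feature engine emits 494
named features across six families:

| family | prefix | content |
|---|---|---|
| shape | `shape.*` | area, weighted-step perimeter, inertia-ellipse axes, eccentricity, length/width ratio, orientation, circularity, 7 Hu moments, 10 Fourier descriptors |
| texture | `texture.*` | 13 Haralick measurements of per-nucleus gray-level co-occurrence matrices (G = 8, four offsets, symmetric, per-nucleus min–max quantization) |
| architecture | `graph.delaunay.*` | edge-length / triangle-area / degree statistics of the centroid Delaunay triangulation (Bowyer–Watson) |
| local neighborhoods | `graph.ccg.shape.*` | cell-cluster-graph (CCG) per-cluster shape statistics; edges by the decaying link rule d^(−α) ≥ r |
| orientation disorder | `graph.cgt.*` | structure-tensor coherence/disorder over CCG neighborhoods and the patch entropy of nuclear orientation (18 × 10° bins, bits) |
| cellular diversity | `graph.rle.*`, `diversity.*` | cell run-length statistics along Delaunay edges and Haralick-style summaries of the cell-cluster co-occurrence morphology matrix (cCCM) |

Every per-nucleus descriptor is aggregated patch-wise with ten first-order
statistics (population-variance convention). Downstream:

* `wrst_rank()` / `select_top_k()` — Wilcoxon rank-sum (Mann–Whitney U)
  feature ranking, exact for small samples, top-5 selection by default;
* `stage_model()` — patient-level 80/20 split, z-scored top-k features,
  500-tree random forest trained per patch, patient stage by
  patch-majority vote; ROC-AUC via the Mann–Whitney identity
  AUC = U/(n₁n₂);
* `km_estimate()`, `logrank_test()`, `concordance_index()`,
  `cox_wrapper()` — product-limit survival curves, 1-df log-rank,
  Harrell's c, and a thin Cox adapter over the survival package;
* `hierarchical_cluster()`, `embed_2d()`, `cohort_report()` — Ward
  clustering of patient profiles, UMAP/PCA embedding, and heatmap /
  violin / scatter / KM reporting with a JSON summary.

A built-in generator (`archetype_presets()`, `generate_patch()`,
`generate_cohort()`) simulates cohorts with ~30 (±10) nuclei per
1000×1000 patch in three archetypes — stage II, peritoneal stage IV, and
hematogenous stage IV — with stage IV nuclei uniformly larger, more
disordered in orientation and more variable in internal contrast, and the
peritoneal class intermediate but nearer stage II. User-supplied
PNG/TIFF patches with label masks are supported through a CSV manifest
(`read_manifest()`, `features_from_manifest()`), and a classical
watershed segmenter (`watershed_segment()`) produces masks when none
exist.

## Worked example

```r
library(nucmorph)

## 1. simulate a small cohort (two stages, survival attached)
cohort <- generate_cohort(c(stage2 = 12, stage4_hematogenous = 12),
                          patches_per_patient = 3, seed = 42)

## 2. extract the feature table (one row per 1000x1000 patch)
feats <- cohort_features(cohort)

## 3. fit the stage classifier: WRST top-5 + random forest + patch voting
model <- stage_model(feats, seed = 42)
print(model)
#> Nuclear morphometry stage classifier
#>   classes: stage2 vs stage4_hematogenous (positive: stage4_hematogenous)
#>   top-5 features: shape.perimeter.min, shape.circularity.mean,
#>     shape.circularity.median, shape.major_axis_len.mean,
#>     shape.major_axis_len.median
#>   held-out patients: 4;  patch-vote accuracy 1.000;  AUC 1.000

## 4. survival by predicted risk group
votes <- predict(model, feats)
surv <- cohort$patients[match(votes$patient_id,
                              cohort$patients$patient_id), ]
lr <- logrank_test(surv$time, surv$event, votes$predicted)
cx <- cox_wrapper(surv$time, surv$event,
                  as.integer(votes$predicted == "stage4_hematogenous"))
#> log-rank chi-sq = 0.56, p = 0.4553
#> HR = 1.39 (95% CI 0.58-3.30), c-index = 0.59
```

The five selected features are all nuclear-size/shape statistics here —
at this toy size (24 patients) the size effect dominates; the 150-patient
recovery experiment in the test suite shows texture (contrast-driven) and
shape families sharing the top ranks, with held-out patient AUC ≥ 0.90.
The survival fit is deliberately under-powered at n = 24: with the
default simulated hazard ratio of 2, the confidence interval (0.58–3.30)
covers the truth but spans 1.

## Vignette

`vignettes/nucmorph-methods.Rmd` documents the generative model and its
calibration, every feature family's exact conventions (quantization,
perimeter weights, angle conventions, graph parameters), the
classification protocol, and known limitations.
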