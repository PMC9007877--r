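---
title: "Nuclear morphometry for stage classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry for stage classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucmorph)
```

# Scope

nucmorph implements a quantitative histomorphometric analysis (QHA)
pipeline for colon-cancer nuclei: per-nucleus and per-patch feature
families (shape, co-occurrence texture, graph architecture, orientation
disorder, cellular diversity), Wilcoxon rank-sum feature selection, a
random-forest stage classifier with per-patient patch-majority voting, and
downstream clustering, embedding and survival analysis. Because the
clinical whole-slide cohorts behind such studies are not distributable,
the package ships a synthetic nuclei-cohort generator whose defaults
emulate the structure described in the colon-cancer QHA literature:
roughly 30 (±10) nuclei per 1000×1000 patch, stage
IV nuclei uniformly larger with more disordered orientation and a wider
spread of internal contrast, and peritoneal stage IV intermediate between
stage II and hematogenous stage IV. Learned segmentation and tumor
localization are out of scope; a classical watershed segmenter is provided
for label masks when none are supplied.

# The synthetic cohort generator

Each archetype (class) is parameterized by `archetype_params()`:

* **area** — lognormal(`area_log_mean`, `area_log_sd`) in px². Presets:
  stage II mean ≈ 442 px² with the widest relative spread (σ = 0.45),
  peritoneal ≈ 466 px² (σ = 0.40), hematogenous ≈ 520 px² (σ = 0.28).
  Absolute magnitudes are a design choice — published per-class feature
  summaries are normalized to 0–1 and do not fix raw scales — chosen once
  so that a ~470 px²
  nucleus (21-px major axis at aspect 2) is a plausible colonic tumor
  nucleus at 40× magnification.
* **orientation** — von Mises around a *per-patch* random direction with
  concentration κ (8 / 6 / 2 across presets), folded to [0°, 180°). A
  per-patch mean direction (rather than a global one) makes
  orientation-entropy features measure within-patch disorder, which is
  what the cell-graph-tensor features quantify.
* **contrast** — each nucleus draws a contrast amplitude c ~ |N(10, s)|
  with class-specific spread s (3 / 5 / 20). Interior intensity is a dark
  base (100) plus a fixed-amplitude smooth gradient along the major axis
  (±15, a chromatin-like structure) plus white noise of amplitude c, on an
  8-bit scale with background 200 ± 3. The gradient matters: co-occurrence
  features are computed after per-nucleus min–max quantization, which
  removes absolute amplitude, so pure white noise of any amplitude would
  look identical. With a smooth component of fixed size, c controls the
  rough-to-smooth ratio — exactly what normalized co-occurrence contrast
  measures — giving the generator a monotone, realizable contrast effect.
* **density** — nucleus count ~ Poisson(30 · (patch/1000)²) in all
  presets, matching the per-patch nucleus count typical of tumor-region
  patches at this scale.

Nuclei are placed by rejection sampling with non-intersecting bounding
circles (at most 100 attempts per nucleus; failures shrink the patch's
count with a warning, never an infinite loop). Real nuclei touch and
overlap — resolving that is the job of the out-of-scope learned
segmentation — so the generator deliberately produces disjoint nuclei:
the feature engine consumes label masks and is thereby isolated from
segmentation quality.

All geometry is drawn before any pixel noise, so label masks and truth
tables are identical whether or not the image is rendered
(`render_image = FALSE` is used when only counts or ground truth are
needed). Everything is reproducible from a single integer seed; cohort
patches carry derived sub-seeds so any patch can be re-materialized
lazily.

Survival times are exponential with class-specific hazard (default:
stage II median 60 months, hazard ratio 2 for stage IV) and independent
exponential censoring — the simplest model satisfying the proportional
hazards assumed by the downstream Cox and log-rank stages.

**Effect-size calibration.** The three injected effect axes (size,
orientation disorder, contrast spread) were calibrated once against the
measured per-patch standard deviations of their carrier features so that
each separates stage II from hematogenous stage IV by roughly 2–4
patch-level SDs. The texture response to the contrast parameter is
non-monotone and saturating, so the peritoneal preset was placed on the
*measured response scale* rather than midway in parameter space; at the
defaults the peritoneal class centroid lies between the other two and
closer to stage II in the selected-feature subspace, consistent with the
intermediate nuclear phenotype described for peritoneal spread.

**What the generator does not emulate:** H&E color, stromal and immune
cells, touching/overlapping nuclei, slide-level spatial heterogeneity,
scanner artifacts. Passing tests therefore demonstrate that the pipeline
recovers *injected* effects from clean masks — not that any particular
real-cohort performance is reproduced, which would require the clinical
slides themselves.

# Feature families

All per-nucleus descriptors are aggregated to the patch level with ten
first-order statistics (mean, median, sd, variance, min, max, range,
min/max ratio, skewness, excess kurtosis), using the population
(divide-by-n) variance convention. Patches with fewer than
`min_nuclei = 5` usable nuclei are skipped. Border-touching nuclei are
excluded from shape/texture aggregation (truncated contours bias those
descriptors) but their centroids remain valid graph nodes. Coordinates
are 0-based (row, col); bounding boxes half-open.

**Shape** (`shape.*`, 250 features): area; perimeter by weighted boundary
steps along the traced Moore contour (1 lateral, √2 diagonal — the
convention matters because circularity 4πA/P² depends on it; rasterized
disks exceed 1 by at most ~10%); major/minor axis lengths as
4√eigenvalue of the pixel-coordinate covariance (ellipse-of-inertia
convention, minor axis floored at 1 px for 1-px-wide degenerates);
eccentricity; length/width ratio; orientation in [0°, 180°) measured from
the +col axis; circularity; Hu's 7 invariant moments; and 10 Fourier
descriptors — magnitudes of contour harmonics 2..11 normalized by the
first harmonic, hence translation/rotation/scale/start-point invariant.

**Texture** (`texture.*`, 130 features): per-nucleus gray-level
co-occurrence matrices at G = 8 levels over the four offsets (0,1), (1,0),
(1,1), (1,−1), symmetrized and normalized; 13 classical Haralick
measurements with base-2 logarithms (0·log 0 := 0). Quantization is
per-nucleus min–max: texture is measured relative to the nucleus's own
range, making the features capture *local* nuclear contrast. For integer
images levels are ⌊(I−min)·G/(range+1)⌋, which reverses exactly under
intensity inversion whenever range+1 is a multiple of G — difference-based
measurements are then inversion-invariant by construction. The headline
`texture.contrast.variance` is the population variance, across a patch's
nuclei, of per-nucleus Haralick contrast.

**Architecture** (`graph.delaunay.*`, 30): Delaunay triangulation of
nucleus centroids by Bowyer–Watson insertion (the super-triangle sits 10⁴
spans out so near-collinear hull slivers survive; flatter triples are
numerically collinear at patch scale and are dropped), summarizing edge
lengths, triangle areas and node degrees. Duplicated centroids are merged;
collinear sets yield missing-flagged features.

**Cell cluster graph** (`graph.ccg.shape.*`, 60): pixel distances are
expressed as percent of the patch diagonal, so typical neighbor spacings
(~6 at default density) exceed 1 and the decay weight d^(−α) lies in
(0, 1). The deterministic rule links u,v iff d^(−α) ≥ r (defaults α = 1,
r = 0.1: link radius 10% of the diagonal ≈ 141 px); a seeded probabilistic
mode draws edges with probability min(1, d^(−α)). Note that with
distances normalized *below* 1 the deterministic rule is degenerate
(d^(−α) ≥ 1 > r always — a complete graph), which is why the percent
scale is used. α = 0 gives the complete graph by design. Connected
components are the local clusters; per-cluster means and variances of
member area, perimeter and major-axis length are aggregated across
clusters (singleton clusters contribute means only).

**Orientation disorder** (`graph.cgt.*`, 11): per node, the structure
tensor of doubled-angle unit vectors (cos 2θ, sin 2θ) over its CCG cluster
(or its 5 nearest neighbors when the cluster has < 3 members) gives
coherence (λ₁−λ₂)/(λ₁+λ₂) ∈ [0,1]; disorder = 1 − coherence. The patch
orientation entropy is the Shannon entropy (bits) of the θ histogram over
18 equal 10° bins — 0 when all nuclei align, log₂18 ≈ 4.17 at uniformity,
and invariant to bin-aligned rotations.

**Cell run-length graph** (`graph.rle.*`, 5): nuclei binned into 4
equal-frequency area bins; runs are maximal same-bin paths walked greedily
(shortest available Delaunay edge to an unvisited same-bin node, nodes
marked visited, started from each unvisited node in index order). The
bin × length matrix yields short/long-run emphasis, bin and run-length
nonuniformity, and run percentage. The greedy-walk construction is a
deterministic surrogate — the original construction is not specified in
the available material — and is isolated behind this module so it can be
swapped without touching other feature code.

**Cellular diversity** (`diversity.*`, 8): the local cell-cluster
co-occurrence morphology matrix (cCCM) counts morphology-bin pairs among
cluster co-members (off-diagonal counts split symmetrically), normalized
to sum 1, then summarized by texture-style energy, entropy, contrast and
variance; computed on 4 equal-frequency bins of both nuclear area and
per-nucleus Haralick contrast.

# Feature selection and stage classification

`wrst_rank()` applies the two-sample Wilcoxon rank-sum test per feature on
per-patch rows labeled with their patient's stage. Groups smaller than 9
(without ties) use the exact U null distribution; otherwise the
tie-corrected normal approximation with continuity correction. Features
are ordered by ascending p, then descending |z|, then name — a fully
deterministic ranking. The default `k = 5` features go to the classifier,
matching the candidate limit used to avoid dimensionality and overfitting.

`stage_model()` is the package's central fit: a *patient-level* stratified
80/20 split (patch-level splitting would leak a patient's patches across
the split), ranking and z-scoring computed on training patches only, a
500-tree random forest (√p features per split, fixed seed) trained per
patch, and held-out patients classified by majority vote over their
patches with even splits broken toward the class with higher mean
predicted probability. The patient risk score for ROC purposes is the
mean predicted positive-class probability; `roc_auc()` computes the
empirical ROC whose trapezoidal area equals the concordant-pair fraction
(the Mann–Whitney identity AUC = U/(n₁n₂), asserted in the tests).

# Downstream cohort analysis

Patients are represented by the mean of their patch feature vectors.
Hierarchical clustering uses Ward linkage on Euclidean distances of
z-scored profiles, cut at k = 3 to separate the three archetypes; 2-D
embedding uses UMAP when uwot is installed and otherwise the first two
principal components, with the method used recorded on the result. The
Kaplan–Meier estimator, the 1-df log-rank test and Harrell's concordance
index are implemented directly (at tied times an event precedes a
censoring; tied risks count ½; tied event times are not comparable) and
are cross-checked in the tests against the survival package; the Cox
proportional-hazards fit itself is a thin adapter over
`survival::coxph()`, by design.

# Numerical choices and degenerate inputs

* Constant features get p = 1 and a flag; constant descriptor vectors get
  sd 0 with skewness/kurtosis reported as 0 and flagged.
* A degenerate single-entry co-occurrence matrix has entropy 0 and its
  undefined correlation is reported as 0 with a flag.
* Nuclei below 10 px are dropped and counted; blank or constant images
  yield all-background watershed masks with a warning.
* The generator's placement cap, the Bowyer–Watson super-triangle scale,
  and the 1-px minor-axis floor are each chosen to fail soft and are
  exercised by tests.

# Problem sizes used by the test suite

The suite exercises the full pipeline at desk scale: the recovery
experiment uses 50 patients per class × 3 classes × 5 patches of
1000×1000 px (seed 11), generator calibration uses 200 default patches,
and the property suites run on small enumerable cases (n ≤ 12 point sets,
n ≤ 8 exact rank-sum enumeration, 100-matrix texture oracles). These
sizes make the whole suite run in a few minutes on one CPU while leaving
every statistical check well-powered.

# Known limitations

* Feature totals are config-driven (494 at defaults), far below the tens
  of thousands extracted from real slides; the inventory covers each
  family but not every scale/offset combination.
* The synthetic generator's clean, disjoint, ellipse-shaped nuclei make
  segmentation trivial by construction; watershed performance on real
  H&E patches will be worse, and the package does not attempt learned
  segmentation.
* With hundreds of strongly separating statistics per family, the exact
  composition of the top-5 list is cohort-dependent; what is stable (and
  asserted) is that the selected features carry the injected effect
  families and that held-out patient-level discrimination is high.
* The Cox stage is univariate/low-dimensional by design; multivariate
  models with clinical covariates are out of scope.
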