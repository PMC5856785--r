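---
title: "Methods: a CT radiomics signature for visceral pleural invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CT radiomics signature for visceral pleural invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radvpi)
```

## The problem

Visceral pleural invasion (VPI) — tumor growth beyond the elastic layer of
the visceral pleura (PL1) or to its surface (PL2) — upstages a small lung
adenocarcinoma from T1 to T2 and carries a worse prognosis, yet it is a
pathological finding that is hard to call from CT morphology alone.
`radvpi` implements a quantitative alternative: a radiomic signature. A
segmented tumor volume of interest (VOI) on thin-section CT is reduced to
a 308-dimensional feature vector; a three-stage filter distils the stable,
non-redundant, discriminative features; an RBF-kernel support-vector
machine turns them into a single probability-scale score `Pi`; and an
ROC-derived cut-off splits patients into high- and low-risk groups.

Because the clinical CT cohort behind this design is private, the package
ships a synthetic-cohort module that reproduces the *published study
conditions* — the per-class feature means and SDs of the five top-ranked
features, and the cohort sizes (192 VPI-negative, 135 VPI-positive) — so
every stage can be exercised, tested and benchmarked end to end.

## The feature catalog (308 features)

* **Shape (8)** — longest 3D diameter (maximum pairwise distance between
  surface-voxel centers, mm), volume, mesh surface area, sphericity,
  compactness, elongation, flatness, surface-to-volume ratio. The surface
  mesh follows the classic marching-cubes convention: each 2×2×2 cell of
  voxel centers is triangulated according to which corners are inside the
  mask, with vertices at edge midpoints; the per-configuration triangle
  table is frozen in the package source. On a digital ball of radius 8
  voxels this yields sphericity 0.93 (the discretized surface is genuinely
  rougher than the ideal sphere).
* **Histogram (9)** — mean, variance, skewness, excess kurtosis, and the
  1st/10th/50th/90th/99th percentiles of in-mask intensity. Percentiles
  use linear interpolation between order statistics; moments are
  population moments (divide by *n*). `Perc.10%` is the point below which
  10% of the voxel values lie.
* **Texture (271)** — computed on intensities quantized to 64 gray levels
  by equal-width binning of the in-mask min–max range. Gray-level
  co-occurrence matrices are accumulated per axial slice for 20 in-plane
  offsets (four directions `(0,d)`, `(d,0)`, `(d,d)`, `(d,-d)` at
  distances 1–5), symmetrized and normalized after summing over slices;
  12 statistics each gives 240 features (`S(0,1)SumAverg` is the mean of
  the gray-level sum distribution for the offset one pixel to the right,
  `S(3,3)Contrast` the inertia for the diagonal offset at distance 3).
  Run-length matrices in the four in-plane directions contribute 7
  statistics each (`45dgr_GLevNonU` is the gray-level non-uniformity of
  the 45° runs), plus 3 aggregates on the runs pooled over directions:
  240 + 28 + 3 = 271.
* **Wavelet (20)** — energies of the LL/LH/HL/HH subbands at scales 1–5 of
  a 2D coiflet-1 transform applied to every axial slice of the mask
  bounding box.

The 240/31 split of the texture block is the package's reconstruction of
the published total of 271; the catalog is generated programmatically, so
other splits are possible without touching the extraction code.

## Feature selection

1. **Reproducibility.** Every feature is extracted twice per lesion — in
   practice from two readers' segmentations, in the synthetic module from
   a perturbed re-segmentation (mask dilated or eroded by one voxel plus
   Gaussian HU noise). Agreement is measured by the concordance
   correlation coefficient
   `ccc = 2·rho·sx·sy / (sx² + sy² + (mx − my)²)`, evaluated with
   population moments. Features with `ccc ≥ 0.9` are kept, best first,
   capped at 100.
2. **Redundancy.** On standardized features, any pair closer than 0.05 in
   correlation distance `1 − |r|` loses its less reproducible member
   (later catalog order on ties). "Nearest-neighbour distance" is not
   further specified in the source material; correlation distance is this
   package's definition, chosen because it is scale-free and symmetric.
3. **SVM-RFE.** A linear maximum-margin classifier is trained repeatedly;
   at each step the feature with the smallest squared weight is removed.
   The contribution weight ω of a feature is its squared weight at
   elimination, normalized to sum 1; the signature uses the shortest
   top-of-ranking prefix whose cumulative ω reaches 0.80 (a fixed-k mode
   is also exposed). The linear SVM uses `cost = 0.01`: with ~100
   candidate features and ~300 cases, a heavily regularized margin
   shrinks toward the class-centroid direction, which keeps the weight
   ordering stable so that weak but real effects are not eliminated early
   by chance fluctuations of noise-feature weights. The final classifier
   is RBF, which offers no per-feature weights, so ranking by linear
   margins is a deliberate divergence between ranking and classification
   models.

## The signature model

The classifier is an SVM with RBF kernel
`k(x, x') = exp(−γ |x − x'|²)`. Features are standardized with the
training split's means and population SDs. The raw decision value `x` is
mapped to the probability scale with the logistic sigmoid
`Pi = 1 / (1 + exp(−x))`; no additional calibration is applied, so `Pi`
is a monotone relabelling of the margin (AUC is identical on both
scales) rather than a calibrated posterior.

Validation uses **10-times-repeated stratified 10-fold cross-validation**:
per repeat every case is validated exactly once; the reported per-case
signature is the mean `Pi` over the 10 repeats. The phrase "leave-one-out
ten-fold" that sometimes labels this design is self-contradictory; the
repeated-stratified reading is the only one in which each case is used
once per repeat as a validation sample. Inside every training split the
standardization, redundancy pruning, RFE ranking, cumulative-ω selection
and an inner stratified 3-fold grid search over
`cost ∈ {0.1, 1, 10, 100}`, `γ ∈ {0.001, 0.01, 0.1, 1}` are re-run, so no
information flows from a validation fold into its model; the test suite
asserts this by corrupting validation labels under a fixed fold
assignment and checking that the out-of-fold decision values do not move.

The risk cut-off maximizes the Youden index (sensitivity + specificity −
1) over midpoints between consecutive distinct `Pi` values, breaking ties
toward the higher cut-off (higher specificity). It is reported on both
the probability scale and, through the inverse sigmoid, the decision
scale; published figures that pair a decision-scale cut-off with a `Pi`
value inconsistent with the sigmoid cannot both be honored, so this
package commits to the literal sigmoid on both scales.

## Evaluation statistics

AUC with DeLong standard error and CI (and paired DeLong curve
comparison) via pROC; accuracy, sensitivity, specificity, PPV, NPV and
likelihood ratios from the 2×2 table at the cut-off (percentages);
univariate logistic regression for the high-vs-low-risk odds ratio with
Wald p, AIC `2k − 2·logL` and a clearly-labelled McFadden pseudo-R² (an
"AIC percentage" is not a defined quantity, so the package reports the
standard AIC and the normalized fit index separately); the concordance
index by pair counting with ties at ½ (identical to the AUC for binary
outcomes, asserted in tests); Mann–Whitney (exact for ≤8 untied
observations per group) and Wilcoxon signed-rank (exact for ≤12 nonzero
untied differences) tests; and per-category chi-square (1 df, no
continuity correction) contingency summaries with percentages rounded to
one decimal.

## The synthetic cohort: what it does and does not emulate

`generate_feature_cohort()` draws the five named informative features
per class from independent Gaussians with the published per-class means
and SDs (an optional equicorrelation knob exists but defaults to 0 —
the simplest model consistent with the published summary statistics),
plus class-blind Gaussian noise features. `generate_image_cohort()`
builds ellipsoidal nodule phantoms on a noisy lung background whose
classes differ by an intensity shift and by the correlation length of a
Gaussian-smoothed texture field; `perturb_segmentation()` emulates a
second reader by ±1 voxel mask morphology plus HU noise, since
inter-reader variability was never quantified in the source cohort.

These generators reproduce *distributional* study conditions, not CT
physics: no reconstruction kernel, no pleural contact geometry, no
correlated feature blocks beyond the optional knob, and the noise
features are exactly exchangeable between classes. Passing tests
therefore demonstrate that the pipeline recovers signal it is pointed
at, controls leakage, and stays at chance on null data — not that it
reproduces clinical accuracy on real patients. Headline clinical figures
(accuracy 90.5%, AUC 0.938, odds ratio 12.01, concordance 0.895) were
measured on a private 327-patient cohort and are not reproducible at
desk scale; they are deliberately not asserted anywhere.

## Numerical choices and problem sizes

* Percentile convention frozen to linear interpolation (type 7);
  population moments everywhere (CCC, histogram, standardization), which
  also makes model fitting invariant to duplicating training rows.
* Wavelet transform: periodized (circular) orthonormal coiflet-1 DWT on
  the bounding box padded to a multiple of 2⁵ with the in-mask mean.
  Periodization keeps the transform exactly orthonormal (subband
  energies sum to the input energy, asserted to 1e-6), which symmetric
  extension would break; energies average the squared coefficients whose
  dyadic support touches the mask, over mask-bearing slices.
* Quantization: 64 equal-width levels over the in-mask range
  (configurable); a constant region maps to level 1.
* Degenerate inputs: empty masks error; single-voxel masks return
  defined shape values (volume, diameter 0) with NA sentinels for
  undefined ratios, and texture features that admit no voxel pair are
  returned as NA rather than aborting the extraction.
* Determinism: every stochastic stage takes a seed; the pipeline derives
  per-stage seeds from one master seed by hashing the stage name, and
  rerunning a configuration reproduces artifacts byte for byte.
* Test and benchmark sizes are chosen to keep the whole suite in a few
  minutes on one core: the reference cross-validation runs on a
  270-case synthetic cohort (160 + 110) with 100 features, the null
  control on 100 cases, oracle equivalence suites on 6×6×3 grids, and
  the RFE recovery study on the full 327-case condition over 25–50
  seeds.

## Known limitations

* Texture is computed per axial slice with in-plane offsets (matching
  the `S(d1,d2)` / `45dgr` naming conventions of the clinical
  literature); a 13-direction fully 3D mode is deliberately not the
  default.
* `Pi` is uncalibrated; its cut-off is data-derived and should be
  revalidated on any new cohort.
* The CCC stage needs genuine replicate extractions; with none supplied
  the pipeline proceeds without a reproducibility filter.
* Automatic lesion segmentation is out of scope: masks are inputs.
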