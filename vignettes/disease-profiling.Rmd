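---
title: "Single-cell morphological disease profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell morphological disease profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnprofile)
library(dplyr)
```

## The problem

Histopathological studies of neurodegeneration traditionally score one
hand-picked measurement, averaged over all cells of an animal or donor.
Both choices throw information away: high-content microscopy yields
hundreds of morphological measurements per cell, and disease tissue is a
*mixture* — even in a severely affected animal many motor neurons (MNs)
are still healthy, so population averages dilute the sick-cell signal.

`mnprofile` implements the downstream statistics for this setting. The
input is a cells-by-measurements feature table (CellProfiler-style
exports: area-shape, texture and intensity measurements per cellular
compartment and stain channel) plus per-cell annotations (animal/donor,
condition, stain panel). Segmentation and measurement extraction are out
of scope — measurements arrive precomputed.

The pipeline has five statistical stages:

1. **Spectral decomposition** — standardize measurements, SVD, explained
   variance, spectrum entropy.
2. **Component–phenotype association** — random-intercept linear mixed
   models over animals.
3. **Subpopulation classification** — a label-independent Gaussian
   mixture on selected components, and label-dependent logistic
   regression (LR) and one-hidden-layer perceptron (MLP) classifiers,
   including condition-censored variants (sLR/sMLP).
4. **Disease scoring** — per-cell probability `P` and severity `S`,
   per-animal aggregation, Welch group tests, and classifier-based
   re-labeling of cells.
5. **Interpretation** — per-measurement relative contributions,
   category-level tests, top-contributor ranking, and hierarchical
   clustering of cells and classifiers.

## Models and conventions

### Standardization and spectra

Each measurement column is z-scored (sample sd, `n - 1`); constant
columns are dropped with a warning. `decompose()` runs an SVD of the
(centered) standardized matrix and reports all `r = min(cells,
measurements)` components; the explained-variance fraction of component
`i` is `p_i = sigma_i^2 / sum(sigma^2)`. Centering is exposed as a flag
because the spectrum — and therefore its entropy — depends on the
convention; the default (centered) treats components as directions of
variation around the cohort mean. Loading signs are fixed by making each
column's largest-magnitude entry positive, so results are identical
across linear-algebra backends.

The spectrum entropy `H = -(1/ln r) * sum p_i ln p_i` lies in [0, 1]:
1 means variance spread uniformly (information-rich data), 0 means a
single dominant direction. `n_components_for(d, 0.9)` gives the usual
"components to 90% variance" summary.

### Random-intercept mixed models

Cells from one animal share that animal's idiosyncrasies, and condition
labels are constant within animals. Regressing per-cell component scores
on a condition indicator while ignoring this grouping inflates the
type-I error badly (the acceptance script measures ~0.4 at animal-sd 1
for naive per-cell OLS at the nominal 0.05). `fit_random_intercept_lmm()`
fits `y = b0 + b1 x + a_animal + e` by maximum likelihood, profiling the
likelihood down to a 1-D optimization over the variance ratio
`sigma_a^2 / sigma_e^2` (closed-form GLS for fixed ratio; the ratio
optimized on the log scale with the zero boundary checked). The
phenotype test is a likelihood-ratio chi-square with 1 df against the
model without `x`; ML rather than REML because REML log-likelihoods are
not comparable across fixed-effect structures. `lme4` is used as an
independent oracle in the test suite, never as the implementation.

The likelihood-ratio test is asymptotic in the number of animals. With
10 animals its size is near the upper edge of acceptable (~0.07); the
package's calibration checks therefore use 20 groups of 10 cells, where
the measured size settles at ~0.06. No Satterthwaite-style small-sample
correction is attempted.

Contrast schemes: `comALS` codes all disease-mutant cells against
control (the phenotype shared across SOD1 and VCP genetic backgrounds),
`vcpALS` codes VCP-mutant cells against everything else (the dominant
VCP-specific phenotype), `sALS` codes sporadic-ALS donor cells against
control for human post-mortem data. By default the first
`n_components_for(d, 0.9)` components are tested at unadjusted
alpha = 0.05 (Benjamini–Hochberg available via a flag); with ~30–90
tests a false selection or two is expected and tolerated downstream,
since selected components are only starting material for classifiers.

### Classifiers and the disease profile

The Gaussian mixture model is fitted on 1–3 selected component scores by
EM with full covariances, a 1e-6 ridge on each covariance, tolerance
1e-6, and 10 seeded k-means++-style restarts; the best final
log-likelihood wins, making the fit deterministic given the seed.
Condition labels play no role in fitting — they are consulted only by
`orient_sick_component()`, which calls sick the component whose members
contain the larger fraction of disease-tissue cells (ties go to the
smaller-weight component, since sick cells are expected to be a minority
in mixed tissue).

In the pipeline, each component is assigned exclusively to the contrast
scheme where its mixed-model p-value is smaller before choosing GMM
components per scheme. The dominant VCP direction correlates with *both*
indicators (VCP cells sit inside the disease class), so without
exclusivity the comALS mixture would simply re-learn the VCP phenotype.

Logistic regression is fitted by damped Newton/IRLS on the penalized
likelihood (L2 strength `lambda`, intercept unpenalized, gradient
max-norm below 1e-8 at exit). The default `lambda = 1` on standardized
measurements keeps the many-measurements/few-cells regime well-posed.
Unpenalized fits on separated classes are detected (all fitted
probabilities saturated at their labels) and rejected with an
actionable error.

The MLP is a single hidden layer of logistic units (default 25) trained
full-batch with Adam-style adaptive steps on the cross-entropy loss plus
weight decay (default 1e-4, summed-loss convention; biases unpenalized).
A first-order trainer is used deliberately: at 750 measurements x 25
hidden units (~19k weights) quasi-Newton workspaces grow with the square
of the weight count, while full-batch gradient descent stays linear and
converges in seconds at this scale. Initialization and training run on a
private seeded RNG stream, so the same seed and config give bit-identical
weights.

Every classifier emits the per-cell disease profile `(P, S)`: `S` is the
raw log-odds-scale score (LR: the linear predictor; MLP: the output
pre-activation; GMM: the weighted sick-vs-healthy log-density ratio) and
`P = plogis(S)` (for the GMM this equals the posterior by construction).
`P` answers "is this cell sick?" but saturates near 0 and 1; `S` keeps
ranking cells within the saturated regime and is the severity readout —
two cells with `P` indistinguishable from 1 can differ by many log-odds
units.

Evaluation defaults to one in-sample ROC over all cells, matching the
single-ROC-per-classifier reporting the pipeline is built around; with
hundreds of measurements and ~120 cells this is optimistic, so
`loao_profile()` offers leave-one-animal-out cross-validation for honest
generalization across animals. The AUC is computed exactly as pairwise
concordance with ties counted one half.

### Disease scoring and re-labeling

Per-animal scores are unweighted means of the animal's cell
probabilities and severities plus the percentage of cells with
`P > 0.5` (the threshold is a config knob; 0.5 is the natural posterior
cutoff). Group differences are tested with two-sided Welch unequal-
variance t tests at the animal level.

`relabel_and_retest()` formalizes the signal-to-noise argument for
single-cell re-labeling: a measurement (e.g. the nuclear/cytoplasmic
intensity ratio of an RNA-binding protein, whose reduction marks
mislocalization) is Welch-tested twice — grouped by tissue origin, and
grouped by classifier verdict (sick vs healthy). When disease tissue
contains healthy cells, origin labels dilute the contrast and the
classifier grouping yields the smaller p-value.

### Contributions

"Which measurements carry the decision" is answered per classifier
family with formulas that are exact for linear models and the standard
path-weight heuristic otherwise: LR uses normalized absolute
coefficients (meaningful because inputs are standardized); the MLP sums
absolute input-to-output path weights through the hidden layer; the GMM
maps the discriminant direction `pooled_cov^-1 (mu_sick - mu_healthy)`
(pooled covariance chosen over per-component for symmetry and stability
in 1–2 dimensions) back to measurement space through the selected
loadings. All contribution vectors are nonnegative, sum to 1, and are
invariant to positive rescaling of the model weights.

Category-level structure is tested two ways: a random-intercept LMM of
per-measurement contributions on the classifier-group indicator with
classifiers as groups (reusing the same mixed-model machinery), and a
permutation test that compares a category's mean contribution with its
distribution under random permutation of category labels (default
10,000 permutations, seeded). If every contribution is identical the
permutation null is degenerate (zero variance); the z-score is then
defined as 0 with a warning rather than NaN.

### Clustering

All hierarchical clustering is UPGMA (average linkage) on Euclidean
distances — over cells (scaled measurements, or `(P, S)` profiles across
classifiers) and over classifiers (contribution or score vectors).
`cut_k()` renumbers labels by first occurrence for determinism, and
`cluster_composition()` summarizes condition make-up per cluster.

## The synthetic-data generator

`generate_cells()` emulates the statistical structure the analysis
assumes, with ground truth, so every stage is testable without any
download:

* animal-level random intercepts `a ~ N(0, sigma_sample^2)` added to
  every measurement of an animal's cells;
* within disease tissue, a sick/healthy mixture: each cell is sick with
  probability `pi_sick` (disease conditions) or `pi_sick_control`;
* a dominant VCP-specific effect direction nested with a subtle shared
  (com) direction: sick cells shift by `d_com` per affected measurement
  on the com support, VCP sick cells additionally by `d_vcp` on the vcp
  support (random-sign unit weights; `d` values are per-measurement
  shifts in noise-sd units);
* CellProfiler-dialect measurement names in three category blocks,
  including designated `Intensity_NCRatio_SFPQ` / `_FUS` columns whose
  support weights are negative (mislocalization lowers the ratio);
* unit Gaussian noise; everything reproducible from one seed.

Defaults mirror the study scale: 3 control / 4 SOD1 / 3 VCP animals,
~12 cells per animal (~120 cells), 750 measurements split 300/250/200
across area-shape/texture/intensity, `d_vcp = 2.0`, `d_com = 0.8`,
`pi_sick = 0.7`, `sigma_sample = 0.5`. The support sizes (`k_com = 40`
on area-shape plus the SFPQ N/C ratio; `k_vcp = 60` on
texture/intensity plus both N/C ratios) are concentrated minorities of
the measurements, echoing how shape descriptors concentrate in the
shared phenotype and texture/intensity (including protein
mislocalization) in the VCP-specific one.

What the generator does *not* emulate: correlated measurement blocks
(real morphological measurements are strongly collinear), heavy-tailed
or skewed measurement distributions, Zernike-moment physics, batch or
staining effects beyond the animal intercept, and cell-level severity
gradation (sickness is binary in the generator, graded only through the
classifiers' scores). Tests passing on this generator therefore
demonstrate correctness of the statistical machinery under its stated
assumptions, not performance on real tissue.

## Numerical and design choices

* **Effect-size reading.** Generator effect sizes are per-affected-
  measurement shifts in noise-sd units (support weights are signs). A
  total-norm reading of the same numbers would make the dominant effect
  a ~0.07-sd ripple per measurement across 750 columns, unable to
  reproduce the qualitative hierarchy (unsupervised clustering isolating
  the VCP-like cells) the pipeline is designed around.
* **Entropy normalization** uses `ln r` with `r` the full reported
  component count, zero-variance components contributing nothing.
* **EM restarts** are seeded deterministically (`seed * 1000 + init`);
  the covariance ridge (1e-6) bounds condition numbers, and a fit whose
  covariance approaches the ridge scale is flagged degenerate.
* **Tie-breaks**: top contributors sort by name on ties; cluster labels
  renumber by first occurrence; the sick-component tie goes to the
  smaller weight.
* **In-sample null AUC.** With p measurements and n cells, in-sample
  ROC optimism scales like sqrt(p/n); the generator's null-discrimination
  check therefore uses few measurements and many cells (6 x ~1200),
  where the in-sample AUC of a null fit is 0.5 within a few hundredths.
* **Problem sizes in the checks.** Calibration and recovery checks use
  20 animals x 10 cells (LMM size), n = 1000 (GMM recovery), n = 5000
  (LR recovery), 100 replicates (re-labeling), and 10,000 permutations
  (category z) — sizes at which the asymptotic properties under test are
  expected to hold while the whole suite stays fast.

## Limitations

* The per-animal severity summary is the mean of cell severities; no
  numeric anchor exists for alternatives (median, trimmed mean).
* The LMM supports one random intercept; no random slopes or crossed
  effects, no small-sample df corrections.
* Contributions are model-linearizations (exact only for LR); no
  SHAP-style attribution, no bootstrap intervals.
* The GMM is restricted to two components in 1–3 dimensions, which is
  the regime the subpopulation model calls for; it is not a general
  mixture tool.
* In-sample AUCs at the default scale (hundreds of measurements, ~120
  cells) are optimistic by construction; use `loao_profile()` when
  generalization matters.
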