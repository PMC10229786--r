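---
title: "Spatial-temporal augmentation for functional brain network classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal augmentation for functional brain network classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbnaug)
library(dplyr)
```

## The problem

Functional brain network (FBN) analysis classifies subjects (e.g. normal
cognition vs. mild cognitive impairment, or depression vs. control) from
resting-state fMRI. After preprocessing, each subject is reduced to a
$t \times m$ matrix $X = [x_1, \dots, x_m]$ of z-scored ROI time series
($m$ atlas regions, $t$ time points; an AAL-template study typically has
$m = 116$ and $t \approx 137$), and the FBN is the $m \times m$ Pearson
correlation matrix of its columns. Clinical cohorts are small — tens of
subjects per class against $m(m-1)/2$ edge features — so classifiers
over- or under-fit. This package enlarges the training set with two
augmentation operators that exploit the structure rs-fMRI actually has,
and fuses the resulting classifiers (the STDAC scheme):

* **Spatial augmentation** uses the anatomical prior that nearby regions
  carry correlated signals. For node $i$, the neighbour set $C_i$ contains
  $i$ plus its up-to-$k$ nearest nodes by centroid Euclidean distance
  $d(\cdot,\cdot)$, restricted to $d(i,s) < r \cdot D$ where $D$ is the
  largest pairwise distance in the atlas and $0 < r < 1$. The augmented
  sample replaces each column with $y_i = \mathrm{mean}(C_i)$, computed
  time point by time point from the *original* columns. The neighbour count
  $k$ is the free parameter: the ladder $k = 1, \dots, \text{degree}$
  yields `degree` distinct samples per subject.
* **Temporal augmentation** draws $l < t$ time points at random *without
  replacement and without contiguity*, keeping the selected rows (one
  shared index list across all ROIs, in ascending time order):
  $z_i = [z_{i1}, \dots, z_{il}]$. Unlike sliding windows, discontinuous
  draws give combinatorially many distinct subsamples per subject, and —
  in the spirit of jackknife resampling — correlation matrices averaged
  over subsamples approach the full-sample estimate.
* **Tensor-score fusion**: one classifier is trained per augmented set;
  at prediction time both score the subject's *original* FBN features,
  producing per-class probability vectors $S_{sp}, S_{te} \in
  \mathbb{R}^c$. The fused feature is
  $\omega = f(S_{sp}^{\mathsf T} S_{te})$ — the flattened
  $c \times c$ outer product, normalized by $f$ (mean removal and scaling
  to unit standard deviation). $\omega$ feeds a third classifier. The
  outer product preserves the joint pattern of the two score vectors that
  plain concatenation would flatten out.

## Estimation and feature choices

The FBN estimator is the raw sample Pearson correlation, with no Fisher
transform, thresholding or sparsification, and the classifier sees the
full strict upper triangle — $m(m-1)/2$ features, row-major order — with
no feature selection. Augmentation, not feature pruning, is the response
to the small-sample problem. The diagonal is dropped because it is
identically 1.

Branch scores are class probabilities for all three supported classifier
kinds (linear-kernel SVM with probability calibration, 500-tree random
forest, one-hidden-layer softmax network with 100 units by default):
fusion multiplies the two vectors, which requires a common nonnegative
scale; raw margins would mix scales between branches. The normalization
$f$ is applied per sample, never per batch, so test-time predictions stay
independent of each other.

The fusion classifier is trained on the fused scores of the *original
training subjects* (each branch scores them after being trained on its
augmented set). This mirrors the test-time contract — at test time only
original samples are scored — and avoids pairing arbitrary spatial with
temporal augmented samples, a pairing that has no canonical definition.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `spatial_degree` | 4 | augmented samples per subject, realized as k = 1..degree |
| `r` | 0.5 | neighbour admission radius as a fraction of the atlas diameter D |
| `temporal_degree` | 100 | random subsamples per subject |
| `l_frac` | 0.7 | fraction of time points kept per subsample (l = ceil(0.7 t)) |
| `l_min_frac` | 0.5 | floor on the kept fraction, preventing overly sparse draws |
| `folds` | 10 | stratified CV folds |

The degrees 4 and 100 are the operating point at which the scheme
performs best in degree sweeps on clinical data; they are also the
defaults here. The radius fraction and the kept fraction have no
published values; `r = 0.5` admits neighbours within half the atlas
diameter before the k-nearest cut, and `l_frac = 0.7` with a 0.5 floor
keeps subsamples long enough that per-draw correlation estimates remain
stable (at `t = 137`, `l = 96`). Whether `l` should be fixed or drawn per
sample is unspecified in the field; it is fixed by default with
`vary_l = TRUE` available.

Spatially augmented samples are *not* re-z-scored before network
estimation: Pearson correlation is invariant to per-column affine maps,
so re-normalization cannot change any downstream result.

## Leakage-safe evaluation

`evaluate_schemes()` compares four schemes under stratified k-fold CV:
`original` (no augmentation), `sda` (spatial only), `tda` (temporal
only) and `stdac` (both plus fusion). The cohort is split *before*
augmentation; only training subjects are augmented, and test subjects
are always evaluated as original samples. Every fold runs a sentinel
(`assert_no_leakage()`) that traces each training row's provenance
(`source_id`) and aborts if any training sample derives from a test
subject. Folds are stratified because per-class counts in these cohorts
are small enough that unstratified folds can lose a class entirely.
Within a joint run the branch models are shared across schemes — the
temporal branch evaluated for `tda` is the same model `stdac` fuses — so
scheme contrasts are paired and the computation is not duplicated.

Accuracy is averaged over folds; precision and recall are computed
per class from the pooled confusion matrix (macro averages are also
reported, since a single-number precision can be aggregated several
ways). ROC and trapezoidal AUC are produced for binary tasks only.

## Interpretation

Discriminative connections are ranked from classifier weights: absolute
linear coefficients for the SVM (summed over the pairwise machines in
multiclass problems), impurity importances for the random forest, and
input-layer weight magnitudes summed over hidden units for the network.
Weight vectors from several models (e.g. CV folds) are averaged, min-max
normalized to [0, 1], and each edge adds its weight to both endpoint
ROIs, so ROI weights sum to exactly twice the edge weights. The top-20
connections are the conventional report; exports include BrainNet-Viewer
`.node`/`.edge` files.

## The synthetic cohort generator

Real cohorts for this problem are access-restricted, so validation runs
on synthetic cohorts. Because Pearson correlation is the analysis
target, second-order structure is the sufficient statistic to emulate:
each subject's rows are i.i.d. draws from a zero-mean multivariate
normal whose correlation matrix is an AR(1)-style base
($\rho^{|i-j|}$, $\rho = 0.1$) plus class-dependent "planted" deltas on
a few disjoint edges, with independent white noise (sd 0.5, attenuating
observed correlations by $1/(1+0.25)$) and per-ROI z-scoring. The
default cohort matches the scale of a small clinical study: 20 subjects
per class, $t = 137$; $m = 30$ keeps the default tests fast, and
$m = 116$ runs the same code unchanged. Geometry is a jittered 3-D grid
standing in for atlas centroids — it is labelled synthetic and has no
anatomical meaning.

What this generator does *not* emulate: haemodynamic autocorrelation,
head-motion artefacts, site/scanner effects, and inter-subject
variability of the base connectivity. Passing tests therefore show that
the pipeline recovers planted second-order group differences under
realistic dimensions and noise — not that any particular clinical
accuracy is reproducible.

## Numerical and design notes

* Neighbour-set ties in centroid distance are broken by ascending node
  index; the admission inequality is strict ($d < rD$). The set always
  contains its centre, so $k = 0$ is the exact identity.
* Temporal draws use one index list for all ROIs; per-ROI independent
  draws would destroy the cross-regional alignment correlation measures.
* All randomness — fold assignment, temporal draws, classifier seeds —
  derives from one master seed; per-(subject, replicate) sub-seeds make
  individual draws reproducible in isolation.
* Degenerate fused scores (zero variance, e.g. two uniform branch
  posteriors) map to the all-zero vector with a warning, not an error.
* A never-predicted class reports precision 0 with a warning.
* Constant ROI columns are an error at load and at network estimation:
  a zero-variance signal has no defined correlation.
* Problem sizes in the validation suite are chosen to exercise the study
  conditions at tractable cost: the scheme comparison uses 3-fold CV
  (the directional contrast between schemes does not depend on the fold
  count; 10-fold remains the default for analysis use), and the null
  calibration uses reduced augmentation degrees because chance-level
  behaviour on a null cohort is degree-invariant.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(n_per_class = 20, m = 30, t = 137, seed = 1)
res <- evaluate_schemes(sim$cohort, sim$geometry, classifier = "svm",
                        folds = 3, seed = 1)
purrr::map_dfr(res, glance)
autoplot(res$stdac)  # ROC for the binary task

fit <- stdac_fit(sim$cohort, sim$geometry, classifier = "svm", seed = 1)
map <- rank_connections(fit$spatial, sim$geometry, top_k = 20,
                        branch = "spatial")
tidy(map)
```

## Limitations

The scheme inherits the assumptions of its inputs: ROI series must
already be parcellated and normalized (no volumetric preprocessing is
done here), the spatial prior is purely Euclidean (no geodesic or
connectivity-informed neighbourhoods), and the fusion is defined for two
branches. Multiclass ROC, nested hyperparameter search and significance
testing between schemes are out of scope.
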