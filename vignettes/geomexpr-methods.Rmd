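---
title: "Geometric landmark features for facial-expression classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric landmark features for facial-expression classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomexpr)
```

# Overview

`geomexpr` classifies the six basic facial expressions — surprise (SU),
sadness (SA), happiness (HA), fear (FE), disgust (DI) and anger (AN) —
from the geometry of 22 anatomical facial landmarks with 3D coordinates
(eyebrows, eye corners, nose saddle/peaks/tip, mouth and chin). The
pipeline has four stages:

1. **Feature extraction**: 89 geometric descriptors per face — 19
   3D distances, 27 3D angles, 23 2D distances and 20 2D angles.
2. **Feature selection**: either PCA variance thresholding or a wrapper
   genetic algorithm (GA) whose objective is cross-validated SVM accuracy.
3. **Class balancing**: SMOTE oversampling to a common per-class count.
4. **Classification and evaluation**: polynomial-kernel one-vs-one SVMs,
   1-nearest-neighbour, and a random-subspace kNN ensemble, scored by
   repeated stratified 10-fold cross-validation.

A synthetic 22-landmark face generator makes every stage runnable and
testable without access to any proprietary face database.

# The feature model

For two landmarks $p_1, p_2$ the distance feature is the Euclidean norm
$d(p_1, p_2) = \lVert p_1 - p_2 \rVert$. Every distance — 2D and 3D
alike — is divided by the distance between landmarks 8 and 9 (the inner
eye corners), a quantity that is stable across expressions; this single
normalizer makes all distance features invariant to uniform scaling.
Angle features take three landmarks, the middle one being the vertex:

$$A = \arccos\frac{(p_3-p_2)\cdot(p_1-p_2)}
      {\lVert p_3-p_2\rVert\,\lVert p_1-p_2\rVert}.$$

2D descriptors evaluate the same formulas on the X–Y projection of the
landmarks, which presumes near-frontal pose; no registration or
reprojection is attempted.

Numerical choices:

* Angles are reported in **radians** and are never normalized — they are
  intrinsically scale-free. Degrees appear only in presentation layers.
* The cosine is clamped to $[-1, 1]$ before `acos`, so floating-point
  rounding on collinear configurations can never produce `NaN` (this is
  fuzz-tested).
* A zero-length angle arm (two coincident landmarks) is an error that
  names the offending descriptor; it cannot occur on valid faces.
* The invariance contract is tested at tolerance $10^{-9}$: the 3D block
  is invariant to any global similarity transform; the 2D block is
  invariant to in-plane similarity transforms and deliberately *not* to
  out-of-plane rotation.

The 89-descriptor catalog and the published 47-descriptor reduced subset
are shipped as editable CSV data files rather than code; count invariants
(89 = 27+19+20+23, 47 = 14+12+8+13) are enforced in tests so that any
transcription damage surfaces immediately. One catalog entry, the 3D
angle `25A3` with vertex at the nose tip between the two inner-eyebrow
points, looks anatomically odd but is transcribed as printed.

The normalizer question — whether 2D distances should be divided by a
2D-projected inter-ocular distance instead of the 3D one — is resolved in
favour of a single 3D normalizer for all distances, the simplest reading
of "all distances are normalized by the landmark 8–9 distance".

# Landmark input formats

Three dialects are supported. Bosphorus-style files carry named points
(header line, count line, then name/coordinate line pairs); the shipped
name table maps 22 of the 24 conventional names to canonical indices 1–22
and ignores the two ear-lobe points, which carry no expression signal.
51-point landmark lists are adapted to the 22-point scheme by copying 19
points and interpolating three (the two nose saddle points and the chin
middle) as midpoints of documented donor points; because interpolation is
affine, adaptation commutes with any global similarity transform. Both
mapping tables are editable CSVs, and the generic long-form CSV/JSON
dialect (one row per landmark) round-trips coordinates exactly.

# Feature selection

## PCA variance thresholding

`pca_select()` performs covariance PCA on mean-centered (not
standardized) features and retains the *minimal* number of leading
components whose cumulative eigenvalue fraction reaches the requested
threshold (the study grid is 97%, 98%, 99%). The "selected features" are
the retained component scores, not a subset of original descriptors.
Tests verify the minimal-count rule on a constructed spectrum with known
cumulative fractions and against an explicit `eigen(cov(X))` oracle.

## Wrapper genetic algorithm

A candidate solution is a binary chromosome of 89 genes (1 = descriptor
included). The configuration mirrors the published setup: population 20,
250 generations (acceptance experiments use a reduced 60), parent
selection as the best two out of five randomly drawn individuals,
one-point crossover at a uniform cut, per-gene bit-flip mutation, and
elitism. Where the setup is underspecified, the defaults are:

* **Mutation rate** $1/m = 1/89$ per gene — the canonical bit-flip rate
  for "simple" mutation; configurable.
* **Tournament sampling** without replacement within a tournament;
  parents may recur across tournaments.
* **Offspring policy**: each tournament produces two children by
  crossover+mutation; ten tournaments fill the population of 20; the
  all-time best individual then replaces the worst offspring, keeping the
  population size fixed and the best-fitness history nondecreasing.
* **Empty chromosomes** get fitness 0 rather than being repaired — they
  can never become the elite.

The fitness of a chromosome is the mean percent accuracy of a
cubic-kernel one-vs-one SVM over stratified 10-fold cross-validation on
the masked columns. Three design choices make this a well-behaved
objective:

* **Fixed folds per run.** The fold assignment is derived from a single
  `cv_seed` and reused for every chromosome, so selection pressure acts
  on a deterministic landscape instead of fold noise.
* **Content-based fold assignment.** Within each class, rows are ordered
  lexicographically by their feature values before fold labels are dealt;
  the assignment therefore depends only on the data values, the labels
  and the seed — not on row order — and fitness is invariant to permuting
  the rows of the input.
* **One standardization, one Gram matrix.** Features are standardized
  once on the full matrix; the polynomial-kernel Gram matrix of each
  candidate subset is computed once and shared by all folds and all 15
  class-pair subproblems. Per-fold restandardization would force ten Gram
  computations per candidate for no benefit to the *ranking* of subsets,
  which is all the wrapper uses. (The user-facing classifiers do
  standardize per training fold.)

The 15 binary subproblems are solved by a compact SMO (sequential minimal
optimization) solver with second-order working-set selection, compiled
C++ shipped in the package. A full GA run evaluates roughly a thousand
unique chromosomes (duplicates are cached), each a complete 10-fold CV;
a general-purpose SVM front end at ~0.5 s per evaluation would make the
wrapper impractical, while the compiled path runs an evaluation in tens
of milliseconds. The solver is validated in the test suite against a
closed-form QP solution on a symmetric XOR toy (where the dual optimum
is analytic) and against `e1071`/libsvm accuracies on shared folds.

The polynomial kernel is $(1 + x\cdot y / d)^{\text{degree}}$ on
standardized features, with $d$ the number of active features — the
stock scaling (`gamma = 1/d`) used by the standard library front ends.
On standardized data an unscaled cubic kernel reaches magnitudes around
$10^5$, which degrades the conditioning of the dual problem; the scaled
kernel is the default a practitioner's tool would apply.

Identical data and configuration (both seeds) give bit-identical GA
results; this determinism contract is asserted in the tests.

# Classifiers and evaluation protocol

* **SVM2 / SVM3**: one-vs-one soft-margin SVMs (box constraint 1, the
  library default, since the source setup relies on tool defaults) with
  quadratic/cubic polynomial kernels; 15 binary machines for 6 classes,
  combined by majority vote, ties to the lowest class index in the fixed
  order SU, SA, HA, FE, DI, AN.
* **kNN "fine"**: $k = 1$ Euclidean nearest neighbour.
* **Subspace kNN ensemble**: 200 weak kNN learners, each trained on a
  without-replacement random draw of $\mathrm{round}(d/2)$ features;
  per-class scores (neighbour fractions) are averaged and the highest
  average wins.

Features are standardized with training-split statistics inside every
fold. `evaluate()` runs `n_repetitions` (default 10) independent
stratified 10-fold cross-validations; the summary statistics (standard
deviation, median, mean, maximum, minimum) range over the repetition
accuracies — the repetition count and the alternative fold-level summary
are both explicit options because the reporting convention leaves them
open. Confusion matrices are pooled over all folds, row-normalized to
percentages in the fixed class order, stored at full precision and
rounded only for display.

SMOTE balancing is applied once to the whole dataset before
cross-validation, mirroring the published protocol ("the classes were
balanced to 104 instances"); per-fold balancing is methodologically
stricter (no synthetic point can straddle a train/test split) and is
available via the pipeline by balancing inside a custom loop, but it is
not the replicated protocol. Each synthetic row lies on a segment between
a class member and one of its five same-class nearest neighbours; the
neighbourhood size follows the canonical default, as the protocol does
not state one.

# The synthetic face generator

The generator deforms a fixed bilaterally symmetric neutral template
(millimetre scale, inner eye corners 33 mm apart) with per-expression
displacement fields that encode the classic qualitative descriptions:
surprise raises the eyebrows and opens the jaw; fear raises and pulls the
brows together; anger pulls the inner brows down and together and presses
the lips; happiness pulls the mouth corners up and back; sadness bends
the inner brows upward with slack mouth corners; disgust raises and curls
the upper lip asymmetrically — the only deliberately asymmetric field.
Each face is `template + activation × displacement + identity jitter +
measurement noise`, followed by a random global similarity transform
(±10° in-plane, ±4° out-of-plane, scale 0.9–1.1, ±20 mm translation).
Activation is Uniform(0.6, 1.4); jitter and noise default to 1.5 mm and
2 mm per axis.

Displacement magnitudes are free parameters; the defaults were chosen
once so that the default configuration (104 faces per class) puts
cubic-SVM 10-fold accuracy in the high-80s-to-mid-90s band — comparable
in difficulty to real landmark data — and were not revisited afterwards.
What passing tests on this generator shows is that the pipeline's
machinery (extraction, selection pressure, protocol) behaves correctly on
data of realistic geometry and difficulty; it does **not** show that the
published database accuracies are reproduced, since the generator shares
none of a real database's identity structure, landmark-detection error
distribution, or inter-class confusability. Out-of-plane pose is kept
small because the 2D feature block assumes near-frontal faces.

## Planted-feature mode

Selection-recovery experiments need data where a known subset of
descriptors — and only it — is informative. Displacing landmarks cannot
deliver that: every landmark participates in several descriptors, so any
class-dependent displacement leaks into features outside the intended
subset. The planted mode therefore works in feature space: it generates
expression-free faces (identity jitter, noise and pose only), extracts
all 89 features — giving realistic values and inter-feature correlations
with no class signal — and then adds class-dependent offsets to ten
chosen columns. The offset signs follow the ten distinct 3-vs-3
bipartitions of the six classes (six classes admit exactly ten), so no
planted feature duplicates another's class information even up to sign.
The offset amplitude defaults to 0.7 within-class standard deviations:
large enough that each planted feature contributes measurable accuracy,
small enough that the fitness optimum stays below 100% — at saturation a
wrapper has no gradient toward including every informative feature and
recovery becomes a coin flip among sufficient subsets.

# Pipeline, seeds and provenance

`run_pipeline()` chains the stages from a nested-list or YAML
configuration and writes features, masks, reduction accounting, the CV
report and a manifest (package version, configuration, derived seeds,
dimensions) into a run directory. All randomness descends from one master
seed through named per-stage child seeds recorded in the manifest;
rerunning an identical configuration reproduces byte-identical reports.
A thin command-line front end (`inst/cli/geomexpr.R`) exposes the stages
as subcommands (`simulate`, `extract`, `balance`, `select-pca`,
`select-ga`, `evaluate`, `reduction-report`, `replicate-ga30`,
`pipeline`).

# Problem sizes used in the shipped experiments

The acceptance experiments run at the sizes the protocol prescribes where
that is stated (SMOTE to 104 per class from the published class counts;
GA recovery at 60 faces per class, population 20, 60 generations, 20
seeded runs; end-to-end evaluation at 104 faces per class with 10×10-fold
CV). Unit tests use 12–30 faces per class, which is ample for contracts
(determinism, invariances, monotonicity) that do not depend on scale.

# Known limitations

* The generator's expressions are linear deformations of one template;
  real databases contain nonlinear, identity-coupled deformation modes.
* 2D features are meaningful only near frontal pose, by design.
* The SMO fitness engine trades per-fold restandardization for speed;
  absolute fitness values can differ from a per-fold-standardized
  pipeline by a fraction of a percentage point, which does not affect
  subset ranking.
* SMOTE before cross-validation (the replicated protocol) lets synthetic
  points share information across folds; accuracy estimates under this
  protocol are optimistic relative to per-fold balancing.
* The published 47-feature subset is shipped as a constant for
  accounting and comparison; re-running the GA on synthetic data selects
  different subsets, as it should — the selected set depends on the data.
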