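---
title: "Methods: representational similarity and decoding of face race and identity"
author: "faceRSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity and decoding of face race and identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceRSA)
```

# Overview

`faceRSA` implements a pipeline for asking where information about face
race and face identity lives in a layered representation — the layers of
a face-trained deep network, behavioural judgements, or multi-voxel fMRI
patterns — and whether that information is biased toward own-race faces.
This vignette is the package's account of the statistical models it
implements, the assumptions they make, the tunable parameters and their
defaults, and the numerical choices behind the code. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# Similarity matrices

The unit of analysis is the representational similarity matrix: for one
layer, the Pearson correlation between the flattened feature vectors of
every pair of images. Flattening is row-major and deterministic in input
order; since Pearson correlation is invariant to any fixed reordering
applied uniformly, the traversal order is a convention, not a modelling
choice. Activations are correlated exactly as supplied — the package
applies no nonlinearity, so callers decide whether pre- or
post-activation tensors are the object of study.

Two numerical conventions matter:

* The diagonal is forced to exactly 1 and the matrix symmetrized by
  averaging with its transpose, avoiding 1 ± ε asymmetries from the
  underlying BLAS.
* A zero-variance feature row has no defined correlation; it is rejected
  with an error naming the offending image rather than propagating
  `NaN`s.

# Decoding: scores, AUC, d′

Race decoding is one-versus-rest: every image (of every race) is scored
by its mean correlation to the target-race images, excluding the
image's own self-comparison. Target-race images form the positive class
and separability is measured as the ROC area under the curve, computed
by the rank-based Mann–Whitney identity with ties credited 1/2. AUC is
converted to sensitivity by d′ = √2 · Φ⁻¹(AUC).

**Clipping.** An AUC of exactly 0 or 1 maps to an infinite d′. Before
the quantile transform the AUC is clipped into
[1/(2PN), 1 − 1/(2PN)], where P and N are the class sizes — half the
smallest non-trivial AUC step the data can resolve. The clip is
symmetric about 1/2, so the antisymmetry d′(1 − a) = −d′(a) survives it.
When class sizes are unknown a fixed ε = 10⁻⁶ is used.

**Tie handling and floating point.** Scores that are algebraically equal
can differ by an ulp or two depending on the order of floating-point
accumulation (the self-excluded mean is computed along a slightly
different path for positive-class and negative-class images). Ranks are
therefore taken on scores rounded to 12 decimals, so exact ties receive
the Mann–Whitney 1/2 credit they should. The rounding is far below any
meaningful correlation difference.

Identity decoding applies the same machinery to the pair correlations of
same- versus different-identity trials, with same-identity pairs as the
positive class.

# Maximum-statistic permutation test

To test decoding against chance while controlling the familywise error
rate across layers, the class labels are permuted once per permutation
and applied **identically to every layer**; the per-layer d′ is fully
recomputed under the permuted labels (both the score vector and the
class memberships), and the maximum d′ across layers is recorded. This
common-permutation scheme is what makes the maximum-statistic null
valid: the null preserves the dependence between layers. One-tailed
p-values use the add-one estimator

p = (1 + #{null max ≥ observed}) / (nPerm + 1),

with "≥" for exceedances, so p is never 0 and the smallest attainable
value is 1/(nPerm + 1). A Bonferroni factor (default 3, one per race
tested) gives the race-corrected p. The default permutation count is
10,000; the tests use smaller counts since the estimator's floor, not
its resolution, is what they exercise.

Two properties worth stating explicitly:

* Under permuted labels the self-excluded score statistic on a strongly
  block-structured matrix is *downward* biased — positives lose their
  own contribution while gaining nothing — so the permuted-label AUC
  averages below 1/2 there. This is a property of the statistic, not an
  error, and it is precisely why the test recomputes the statistic under
  each permutation instead of comparing to a nominal 0.5. On an
  exchangeable (unstructured) matrix the mean permuted AUC is 1/2, and
  the familywise error rate at α = 0.05 is calibrated (the acceptance
  suite measures it across 500 global-null datasets).
* Within one run every source of randomness derives from one integer
  seed; permutation results are bit-for-bit reproducible.

# Parametric contrasts

The per-image within-race minus between-race correlation difference
feeds one-tailed paired t-tests per layer-and-race cell, with the Holm
step-down correction across cells (48 cells at 16 layers × 3 races).
The Holm step is delegated to `stats::p.adjust(method = "holm")`; the
acceptance suite verifies it against an independent step-down
enumeration. Cohen's d is the paired mean difference over the SD of the
differences, or the pooled-SD standardized mean difference for
independent samples. Mixed-design ANOVAs (sphericity corrections, η²)
are deliberately out of scope: the package emits tidy per-cell tables
that any standard ANOVA routine consumes.

# Behavioural RSA and Fisher z

Behavioural similarity for a trial is the proportion of participants
judging the image pair "same". Layer-wise brain/network–behaviour
correspondence is the Pearson correlation between these proportions and
the layer's pair correlations, compared against the one-tailed critical
r at α = 0.05 with n − 2 degrees of freedom (positive correlations are
the directional hypothesis, matching the single dashed criterion line
conventionally drawn in layer-wise RSA figures).

Correlations are compared with the independent-samples Fisher z test.
The package implements the independent form knowingly: when the two
correlations share participants or trials the test is approximate
(generally conservative dependence is not guaranteed), and users
comparing overlapping samples should treat borderline z values with
caution. Fisher transforms clamp |r| at 1 − 10⁻⁷ so noiseless inputs
map to a large finite z rather than infinity.

# ROI definition by flood fill

Regions of interest are grown on a z-statistic volume from a peak voxel
(the global or mask-restricted argmax; ties broken by lowest linear
index). Growth is greedy: among the suprathreshold (z > zMin, default
2.3) face-neighbours of the current region, the highest-z voxel is added
(ties again by lowest linear index) until the target size — default 500
voxels — is reached or no candidate remains. If fewer than 500 voxels
are reachable, the region is cut back to the largest multiple of 100 by
removing the most recently added voxels; because every prefix of the
growth sequence is connected, the trim preserves connectivity, and under
highest-z-first growth the trimmed voxels are the lowest-z ones.

Choices the statistic does not pin down, exposed as configuration:

* **Connectivity**: 6 (face), 18 or 26 neighbourhoods; default 6, the
  most conservative notion of "spatially contiguous".
* **Fallback rounding**: "largest size to the nearest 100" is
  interpreted as rounding down — a 230-voxel reachable set yields a
  200-voxel region; published 200-voxel regions are consistent with
  truncation.
* **Coordinates**: voxel indices are 1-based inside R, but the
  voxel-to-world affine follows the NIfTI 0-based convention; world
  coordinates are reported in mm through the affine.

# LOPO MVPA and adaptation

For pattern analysis, responses are first normalized per participant and
voxel by subtracting the mean across the selected conditions, removing
the shared univariate response so that correlations reflect pattern,
not amplitude. Note one geometric consequence: after centring across C
conditions, the average between-condition correlation is pushed negative
(patterns that sum to zero cannot all correlate positively), so
contrasts should always be read as differences between pair types, not
absolute similarities.

Leave-one-participant-out similarity correlates participant p's pattern
for condition i with the unweighted voxelwise mean pattern of the
remaining same-group participants for condition j, for every ordered
pair (i, j); a Fisher z accompanies every r. The left-out participant
never contributes to their own template (the suite asserts this by
perturbation). Correlations are computed per condition pair and
averaged on the z scale; the alternative — concatenating patterns across
pairs before correlating — is a different statistic and is not
implemented.

Three contrasts summarize the records per participant: Same-Race versus
Different-Race mean z; the own-race-bias 2 × 2 (Face × Participant
group) with its interaction contrast (own minus other race, averaged
over groups) and per-group planned one-tailed paired t with Cohen's d;
and Face–Face versus Face–Object (object–object pairs excluded from
both sides).

Adaptation is deliberately computed on **unnormalized** responses: it is
an amplitude effect — the Different-Identity minus Same-Identity mean
ROI response, positive under repetition suppression — and per-voxel
mean removal would delete it. "Peak response" is operationalized as the
mean parameter estimate over ROI voxels: the inputs are block-level GLM
betas, so a within-ROI mean is the stable choice and a time-course
maximum is not recoverable from them.

# Synthetic generators: what they emulate

The generators produce every input the pipeline consumes, with the
statistical structure the analyses assume planted explicitly, so the
whole pipeline is testable without any external data.

**Features** (`simulateLayerFeatures`). The default configuration mirrors
the target stimulus set: 3 races × 90 identities × 2 images = 540
images over 16 layers, and a pair table of 45 same- plus 45
different-identity trials per race. An image's vector in layer l is

raceSignal(l) · m_race · μ_race + identitySignal(l) · μ_identity + noise,

with race and identity prototypes drawn once per layer from a standard
normal and isotropic Gaussian noise (SD 1 by default). The signal
profiles default to a linear 0 → 1 ramp across layers — the simplest
shape with the qualitative property the analyses probe, namely
category and identity information concentrating in later layers. The
per-race multipliers (default 1, 1, 1) emulate a training-set bias when
raised for one race (e.g. 1.5 for White faces). The generator does not
model image statistics, feature sparsity, or between-layer feature
correspondence; passing tests therefore show the statistics recover
planted structure, not that any real network behaves this way.

**Behaviour** (`simulateBehaviour`). Each of 70 simulated participants
judges every trial independently, with
P("same") = guess + (1 − 2·guess) · logistic(slope · (r − r̄)). Real
observers are not independent Bernoulli machines; the generator provides
the monotone coupling between pair similarity and judgement that the
RSA stage needs, nothing more.

**Voxel patterns** (`simulateVoxelPatterns`). Condition templates mix a
global face component, a race component and a condition-unique component
so that face templates of different races correlate at ρ_between
(default 0.2) and the race-template share is ρ_within (default 0.6,
with ρ_within ≥ ρ_between enforced); the object template is orthogonal
to all face templates. Participant p's pattern for condition c is
baseline + (1 + δ·own(p, c)) · T_c − s·same(c) + noise: δ (the own-race
consistency boost) raises the template-to-noise ratio for own-race
conditions, and s is the planted repetition suppression in response
units. Defaults: 12 participants per group, 300 voxels, noise SD 0.5,
baseline 1, δ = s = 0. The adaptation recovery conditions use 28
participants per group and noise SD 0.3.

**Statistical maps** (`simulateStatMap`). Sums of isotropic Gaussian
bumps plus optional white noise — enough structure to exercise peak
finding, thresholding and flood-fill growth, with no claim to field
smoothness or anatomical realism.

All generators are pure functions of (configuration, seed): reruns are
bit-identical, which the suite asserts at the level of written files.

# Problem sizes in the test and acceptance runs

The statistical properties checked are size-free, so the heavy
simulations run at reduced sizes chosen as this package's own test
conditions: the familywise-error calibration uses 60-image, 40-feature
datasets over 16 layers (500 datasets × 499 permutations) — error-rate
calibration does not depend on image count; signal-recovery runs use
60 images and 100 features over 16 layers across 50 seeds; MVPA
recovery uses 12 + 12 participants × 300 voxels across 100 seeds, and
adaptation recovery 28 + 28 participants. The full 540-image default is
exercised for structure (counts, labels, pair composition) rather than
in the replicated simulations. The White-face decoding advantage is
assessed over layers 5–13: with a ramping signal the final
fully connected layers sit at the clipped d′ ceiling for every race, so
the ordering is only measurable below ceiling — which is also where a
training-set advantage is expected to express itself.

# Known limitations

* The Fisher z comparison assumes independent samples; the package does
  not implement a dependent-correlations test.
* Decoding is correlation-score plus ROC by design; no cross-validated
  classifiers are provided, so results are not comparable to
  classifier-based MVPA accuracies.
* The flood-fill growth order (highest-z-first) and connectivity are
  conventions; other orders produce different but equally "connected"
  regions, and only the documented defaults are calibrated by the
  tests.
* The generators plant linear-Gaussian structure; effect sizes
  recovered from them say nothing about power against real noise
  spectra, participant heterogeneity, or network idiosyncrasies.
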