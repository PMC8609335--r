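---
title: "Between-subject identity decoding with searchlight hyperalignment"
author: "hyperMVPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-subject identity decoding with searchlight hyperalignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperMVPC)
```

## The problem

Different brains encode the same stimulus in idiosyncratic fine-scale
response patterns: a classifier trained on one group of participants'
activity patterns typically cannot decode anything from a new participant
when the data are aligned only anatomically.  Hyperalignment resolves this
by estimating, for every participant, a high-dimensional linear
transformation of that participant's cortical vertices into a common model
space, using response time series to a naturalistic stimulus (here, a
movie) that all participants saw.  If identity information about familiar
faces is encoded in a *shared* neural code, then a classifier trained on
hyperaligned patterns from n − 1 participants should decode face identity
from the held-out n-th participant — and the cortical distribution of that
between-subject decoding, contrasted between personally familiar and merely
visually familiar faces, separates regions carrying visual identity codes
from regions carrying person knowledge.

This package implements that full analysis as reusable, tested components:
cortical geometry with geodesic searchlights and ROIs, carry-over
counterbalanced trial sequences, GLM response-pattern estimation,
searchlight hyperalignment, nested cross-validated multivariate pattern
classification (MVPC), and permutation/bootstrap inference — together with
a synthetic multi-subject generator that provides ground truth for recovery
testing.

## The analysis pipeline

### Surface model and searchlights

Cortical geometry is a triangulated mesh (two disconnected hemispheres)
with a per-vertex medial-wall mask.  Geodesic distance is the shortest path
along mesh edges with Euclidean edge weights — a standard graph
approximation that we can test exactly against all-pairs shortest-path
oracles, rather than exact polyhedral geodesics.  A searchlight is the
geodesic disk of all non-masked vertices within a radius of its center:
20 mm disks for alignment, 10 mm disks for decoding, following the
reference analysis.  ROIs are built from a statistic map by refining seed
peaks to the local maximum within 3 mm, growing 15 mm disks, and assigning
doubly-claimed vertices to the geodesically closer center (ties go to the
earlier seed, with a warning).  Peak eligibility uses a two-stage statistic
threshold (1.96, then 1.65) and errors when neither passes.

Synthetic meshes are subdivided icosahedra.  The tiny test mesh (42
vertices per hemisphere) uses ~3 mm vertex spacing.  The demo mesh (162
vertices per hemisphere) uses ~6 mm spacing so the sphere's geodesic
diameter (~72 mm) is several times the 20 mm alignment radius: a
searchlight is then genuinely *local*, and regions can be placed outside
each other's searchlight reach.  This matters because searchlight
alignment transforms mix vertices within a searchlight: any location that
shares a searchlight with a strong signal region inherits decodable
signal.  That smearing is a real property of the method (it has a ~2 ×
radius reach), visible at desk scale because whole hemispheres fit inside
a few searchlights; we verified that on a sphere smaller than the
searchlight even antipodal "null" locations decode far above chance purely
through transform leakage.  The default synthetic layout therefore places
the core-like system on the left hemisphere and the extended-like system
on the right — hemispheres are disconnected, so no searchlight can bridge
them — and draws the null control ROI on the core hemisphere at maximal
geodesic distance from the core, beyond searchlight reach on the demo
mesh.

### Trial sequence design

Trial orders are Type-1 Index-1 (T1I1) serially balanced sequences over
21 labels (20 face images plus one fixation "null" label): length
21² + 1 = 442, first trial repeated at the end, and every ordered pair of
labels — self-pairs included — appearing exactly once as adjacent trials,
so first-order carry-over effects are balanced.  Our generator constructs
the sequence as 21 chained blocks, each a permutation of the 21 labels
(a Hamiltonian-path decomposition of the complete distinct-pair digraph
with block ends pairwise distinct, consumed self-pairs at the block
junctions, and cyclic closure).  This block structure is what guarantees
that every consecutive window of 21 trials shows all labels, hence that a
63-trial run contains each image exactly 3 times plus 3 fixation trials.
A plain random Eulerian circuit has the T1I1 pair property but *not* the
block property, and the block-balanced object provably does not exist for
alphabets of size 3 (nor, by exhaustive search, 4 or 5), so small
alphabets fall back to a random Eulerian (Hierholzer) construction.  The
randomized block search is implemented in C++ with backtracking across
blocks; a 21-label sequence takes tens of milliseconds, so candidate pools
of hundreds of sequences are generated directly.

Candidates are scored by detection-power efficiency: one parametric
regressor per relationship matrix (same identity, same head view,
mirror-symmetric head view), whose value at trial *t* is the relation
between the labels at *t* − 1 and *t*, convolved with the HRF at TR
resolution; efficiency is the inverse of the summed estimator variances of
those regressors in the resulting design (the time axis is extended 32 s
past the final trial so the full hemodynamic tail is covered, which also
makes efficiency exactly invariant to sequence reversal for symmetric
relations).  A constant relationship regressor (e.g. an all-ones matrix)
is collinear with the intercept and is flagged with efficiency 0.  Runs
are cut from two chained sequences (the second starting on the first's
final label), 63 trials per run, each trial 5 s (3 × 500 ms presentations
with 50 ms gaps, then 3,400 ms fixation), 15 s fixation at both run ends,
and an extra lead trial prepended (run 1 repeats its own first trial;
later runs repeat the previous run's final trial).  How the 883-trial
concatenation reduces to 630 run trials is not fully determined by the
source description; we take the first 630 trials and treat the 63 as
excluding the lead trial.

### GLM response patterns

Nuisance removal is a single joint least-squares projection: per-run
polynomial drift, all discrete-cosine components below 0.0066 Hz, and the
supplied nuisance table (6 motion-like + 6 physiological-like series).
The task design has one HRF-convolved regressor per image per run — for
the full layout, 10 runs × 2 familiarities × 4 identities × 5 views = 400
regressors of interest — plus a pooled button-press regressor, a pooled
lead-trial regressor, and per-run polynomials up to third order.  The HRF
is the canonical double-gamma (gamma(6, 1) − gamma(16, 1)/6, seconds)
convolved with a boxcar of the 1.6 s stimulus duration, rendered on a
16-fold oversampled grid and sampled at TR = 1.25 s.  Estimation is
ordinary least squares in a single model; the per-condition *t*-values
(beta / SE at time-points − regressors degrees of freedom) are the
multivariate features.  No autocorrelation correction is applied; the
*t*-patterns are consumed by a classifier, not by univariate inference, so
prewhitening is omitted as a documented simplification.

### Hyperalignment

Within each 20 mm searchlight, each subject's z-scored movie time series
is aligned to an evolving template by orthogonal Procrustes (SVD solution;
no scaling or translation).  The template is seeded by the reference
subject, updated as a running mean during the first pass, and then all
subjects are realigned to the group mean for the remaining passes (3
total; configurable).  Per-searchlight transforms are summed into a
whole-cortex sparse map; each row is then divided by the number of
searchlights containing that vertex ("mean" aggregation), so that aligning
identical data yields an exact identity application.  Unnormalized "sum"
aggregation is available as a config alternative.  Task patterns are
projected into the reference participant's space by composing the
subject's map with the transpose of the reference's map in one linear
step; because both the projection and the GLM are linear, projecting
estimated patterns equals estimating patterns from projected runs.

### Between-subject MVPC

Hyperaligned patterns are averaged across runs (20 samples = 4 identities
× 5 views per subject and familiarity), then classified in a nested
cross-validation over participants *and* head views: train on n − 1
subjects' samples at 4 views, test on the left-out subject's 4 samples at
the left-out view — 5 × 14 = 70 folds for the full layout, so train and
test are independent at both the subject and the stimulus level.  The
classifier is a linear soft-margin SVM in one-vs-one formation with vote
counting (libsvm via e1071; pairwise decision values are computed from the
dual solution and vote ties are broken by summed decision values, then by
the lowest class index).  The regularization parameter defaults to
C = 1 / (mean squared training-sample norm), scaling with the data norm;
no feature normalization is applied beyond the upstream z-scoring /
*t*-values.  Searchlight mode assigns each 10 mm disk's accuracy to its
center vertex; ROI mode uses ROI vertex sets instead.

### Inference

Identity labels are permuted independently within every (participant,
head view) cell — preserving each cell's label multiset — and the full
decoding is repeated (100 permutations by default).  A bootstrap null for
the mean accuracy draws `nFolds` fold-level accuracies with replacement
from the pooled permuted folds and averages them (10,000 draws in the
full setting; 1,000 in the demo).  Empirical p-values use the
bias-corrected counting rule (exceedances + 1)/(draws + 1), with ties
counted as exceedances; multiplicity is handled by Benjamini–Hochberg FDR.
Difference maps floor each condition's fold-mean accuracy at the 25%
chance level before subtracting (sub-chance values are noise and would
inflate the difference), rebuild the same statistic from independently
bootstrapped permuted folds per condition for the null, and test
two-sided on absolute values.

#### A calibration caveat

Cross-validation folds share most of their training data, so fold
accuracies are positively correlated.  The variance of the observed
mean-over-folds is therefore larger than (pooled fold variance)/nFolds —
we measure an overdispersion factor of about 1.3–1.6 on signal-free
synthetic worlds, roughly independent of the number of subjects — while
the pooled-fold bootstrap null has exactly that smaller variance.  The
resulting one-sided uncorrected false-positive rate at p < 0.05 is about
0.09–0.10 rather than 0.05.  The stratified alternative
(`buildNull(..., stratify = "permutation")`, each draw resampling folds
within a single permutation) keeps the between-permutation spread and errs
on the conservative side (~0.02), because the within-permutation
resampling adds variance on top of it.  Only the raw distribution of
per-permutation means is exactly calibrated, by exchangeability, but it
limits p-value resolution to 1/(permutations + 1), which is why the fold
bootstrap is used in the first place.  The package defaults to the pooled
bootstrap for fidelity to the published procedure and exposes the
stratified variant; BH-corrected conclusions on our synthetic worlds are
unaffected (fully null data yield zero discoveries after FDR), but
uncorrected p-values near threshold should be read with this inflation in
mind.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
with known ground truth:

- A shared latent movie time series and shared condition patterns, mixed
  into each subject's vertex basis by independent random orthogonal
  transforms that are *block-local* (one block per region, large regions
  split at 24 vertices), matching the searchlight locality of the
  alignment model.
- Condition patterns decompose into a view-invariant identity component,
  a view component, and a familiarity offset (each unit variance per
  latent dimension).  Identity components are present in core-like
  regions for both familiarity conditions, in extended-like regions for
  the "personal" condition only, and absent in null regions; null regions
  carry no signal at all.
- Noise is unit-variance Gaussian per vertex and time point (optional
  AR(1) via `arCoef`), added after mixing; region SNR parameters scale
  the signal amplitude.  The defaults (`snrCore = snrExtended = 2`)
  represent a strong, clearly recoverable effect — they are calibration
  knobs for the recovery tests, not claims about effect sizes in real
  data.
- Trial-level runs convolve the condition patterns with the HRF over a
  T1I1 run design and add polynomial drift, loadings on the 12 nuisance
  series, and noise.  A pattern-level shortcut (`emitSubjectPatterns`)
  emits the per-run condition patterns directly; it is statistically
  matched to what the GLM stage estimates and is what the larger recovery
  analyses decode, with the full BOLD→GLM path exercised at small scale.

What passing recovery tests show — and what they do not: the synthetic
world satisfies the method's assumptions by construction (a truly shared
latent code, orthogonal local mixings, Gaussian noise).  Success here
demonstrates that the implementation recovers what the model class can
express; it says nothing about whether real cortical responses satisfy
those assumptions, and real-data properties such as spatial noise
correlations, hemodynamic variability across regions, motion artifacts,
and imperfect anatomical correspondence are deliberately absent.

## Problem sizes used by the test suite

The packaged analyses are scaled to run comfortably on a single CPU: the
tiny fixture (4 subjects, 42-vertex hemispheres, 2 runs) drives unit and
chance-calibration tests; the demo fixture (14 subjects, 162-vertex
hemispheres, 10 runs) drives the full recovery analysis with 50 label
permutations and 1,000 bootstrap draws over the region ROIs; the type-I
calibration uses a signal-free demo-mesh world with 3 subjects, all ~300
searchlights as null locations, and 25 permutations.  The full-size
settings (100 permutations, 10,000 bootstraps, 70 folds) are one argument
away in every function.

## Reproducing the demo analysis

```{r demo, eval = FALSE}
library(hyperMVPC)
res <- runPipeline(pipelineConfig(seed = 1, scale = "demo",
                                  nPermutations = 50, nBootstrap = 1000),
                   outDir = "demo_out")
res$stats$personal      # per-ROI observed accuracy, p, q
res$difference          # floored personal - visual difference map
```

## Known limitations

- Geodesics are graph shortest paths, slightly overestimating true
  surface distances on coarse meshes.
- The GLM assumes white residuals; no REML/prewhitening variant is
  provided.
- The classifier's norm-scaled C reproduces the *behavior* of a
  norm-scaled soft margin but exact equivalence to other default
  implementations is not claimed.
- The pooled fold bootstrap's uncorrected p-values are mildly
  anticonservative (see the calibration caveat above).
- Block-balanced T1I1 sequences do not exist for alphabets of 3–5
  labels; those sizes use plain Eulerian T1I1 sequences without the
  every-n-trials block property.
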