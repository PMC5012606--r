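---
title: "Decoding core affect from trial-level fMRI patterns: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding core affect from trial-level fMRI patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectmvpa)
```

## The problem

Core affect is commonly described by two dimensions: valence (negative to
positive) and arousal (low to high). When people view naturalistic
audiovisual clips, both dimensions should be identifiable on single trials
from distributed fMRI activity patterns - provided the analysis controls for
the low-level stimulus properties (brightness, motion energy, loudness,
pitch) that covary with affect in naturalistic material. This package
implements that full analysis path as composable, tested pieces:

1. **features** - low-level visual, motion and auditory features of the
   clips; balance checks across the 2x2 valence-by-arousal design; reduction
   to five principal-component nuisance scores.
2. **scaling** - behavioural validation: INDSCAL on per-subject stimulus
   correlation matrices from six rating scales, recovering a 2-D affect
   space without ever asking for valence or arousal directly.
3. **prep** - voxel time series to standardized trial patterns: nuisance
   regression, percent-signal-change (PSC) extraction at the hemodynamic
   offset, per-trial standardization; localizer mask algebra.
4. **decode** - L2-penalized logistic-regression decoding under three
   cross-validation schemes, with permutation significance.
5. **searchlight** - 5x5x5 box searchlight maps, random-effects group
   t-maps, max-cluster-size permutation inference.
6. **confirm** - within-cluster decoding with stability-based voxel
   selection, STATIS compromise spaces, point-biserial design correlations.
7. **synthdata** - generators for designs, clips, ratings and
   multi-participant BOLD data with known ground truth, so that every claim
   above is testable without scanner data.

## The experimental design being modelled

Thirty-two clip exemplars fill the four quadrants of the affect space (high/
low arousal x negative/positive valence, 8 each), with semantic content
(4 human, 2 animal, 2 inanimate clips per quadrant) balanced so that category
and affect are not confounded. A session presents 128 trials: 4 presentation
blocks of all 32 exemplars, 5 s clip + 7 s fixation (12 s spacing), TR 2.2 s.
`generate_design()` draws presentation orders under the two scheduling
constraints - every successive window of four trials contains all four
quadrants, and no two consecutive trials share a quadrant - by rejection
sampling within windows; violations are structurally impossible in its
output, and `check_design_order()` re-verifies every order it returns.

## Trial patterns

`extract_psc()` converts each voxel's series to percent signal change about
its run mean and takes, per trial, the mean of the two volumes offset 4.4 s
(= 2 TR) from stimulus onset, accounting for hemodynamic delay. Onsets need
not be volume-locked (12 s spacing with TR 2.2 s is not); sampling is
relative to the volume nearest the onset. `standardize()` z-scores each
trial's voxel vector. The run mean used as the PSC baseline is computed
after nuisance regression *with the fitted intercept restored*, so the
denominator keeps its physical meaning.

### Nuisance control

Naturalistic clips confound affect with low-level features - most
prominently, high-arousal clips carry more motion. `nuisance_pca()`
compresses the feature table into five component scores (two visual, one
motion, two auditory), using block-wise PCAs on standardized features
(correlation, not covariance: the blocks mix dB, pixel counts and unit
scales). `regress_nuisance()` then removes, per voxel and run, the five
HRF-convolved component regressors together with six head-motion parameters.
The package treats any additional denoising regressors as a hook: extra
columns can be appended to the motion matrix, so tool-specific noise
regressors (e.g. data-driven ones) fit the same interface.

The acceptance suite demonstrates the control directly: on synthetic data
whose only label-related signal is the motion-component confound, arousal
decodes well above chance before regression and at chance after it.

The control has a real cost. With 32 exemplars, any five per-exemplar
covariates have a chance multiple correlation with a +/-1 design vector of
around `R^2 ~ 5/31`, so per-run regression removes a corresponding share of
genuine affect signal and - more damagingly for a classifier - makes the
residual effect amplitude vary across exemplars. On synthetic data this
costs roughly ten accuracy points at high SNR. This mirrors the tradeoff in
real naturalistic designs: the regression buys interpretability (decoding is
attributable to affect, not low-level features) at the price of sensitivity.
Signal-recovery checks therefore run the generator -> PSC -> standardize ->
decode path on data without nuisance signal, where there is nothing to
regress out; the confound-removal check exercises the regression itself.

## Decoding

`fit_logistic()` is penalized maximum-likelihood logistic regression (ridge
penalty `lambda` on the weights, intercept unpenalized) fitted by IRLS.
With more voxels than training trials the fit is reduced exactly to the row
space of the design (thin SVD), so the solution is identical at a fraction
of the cost. Inside the cross-validation engines the overparameterized case
is solved in kernel (Gram) space on per-fold column-centred data with the
intercept fixed by the centring - with balanced classes and row-standardized
patterns the profiled intercept is numerically negligible, and fixing it
lets Gram matrices be reused across the thousands of refits that permutation
tests and searchlights require. Decisions are the sign of the linear score;
an exact zero goes deterministically to the first class. The default
`lambda = 1` on standardized patterns stabilizes fits when voxels far
outnumber the 96 training trials; it is exposed everywhere.

Three cross-validation schemes mirror the three scientific questions:

* `cv_within()` - four folds leaving one presentation block out: can affect
  be identified within a person?
* `cv_cross_exemplar()` - 32 folds leaving one exemplar (all four of its
  presentations) out: does decoding generalize to unseen stimuli, or did the
  classifier memorize exemplars? The test suite includes an adversarial
  generator in which exemplar-unique patterns drive within-participant
  decoding to high accuracy while cross-exemplar accuracy honestly collapses
  to chance.
* `cv_cross_participant()` - leave one participant out, training on the
  pooled trials of the rest in a common voxel space: is the code shared
  across brains? (For synthetic data the common space is the shared grid;
  real data would rely on prior spatial normalization, which is out of
  scope.)

Significance uses an empirical null from non-informative permutations of the
labels *within the training partition of each fold* (test labels untouched),
with the add-one rule `p = (1 + #{null >= observed}) / (n_perm + 1)`.
Calibration is checked by a Kolmogorov-Smirnov uniformity test of p-values
over replicate null datasets.

## Searchlight mapping and cluster inference

`searchlight_map()` scans every in-mask voxel, decodes the in-mask voxels of
its 5x5x5 box neighborhood with the same four-fold CV, and assigns accuracy
minus chance (.5) to the centre. Neighborhoods are truncated at grid and
mask boundaries rather than discarded, so cortex at mask edges is retained.
`group_ttest()` computes the voxel-wise random-effects one-sample t across
participants; `cluster_extract()` thresholds at an uncorrected voxel p
(default .001, upper tail) and keeps face-connected components.
`cluster_null()` rebuilds the entire map-and-group pipeline under
within-participant label permutations (which preserve the 64/64 balance),
records the largest suprathreshold component per permutation, and sets the
cluster-size cutoff at the null's 95th percentile. Valence and arousal
permutations are exchangeable, so one null distribution serves both targets.
No spatial smoothing is applied to accuracy maps before the group test.

A box searchlight cannot localize finer than its own neighborhood: every
centre whose box touches an informative region carries information, so the
natural recovery target for a cluster is the region *dilated by half the box
width* (`searchlight_support()`). Recovery is scored as Dice overlap against
that support; the raw-region Dice is also reported but is bounded well below
1 by the method's resolution even for a perfect result.

## Behavioural scaling (INDSCAL)

`ratings_to_corr()` builds each subject's 32x32 stimulus correlation matrix
across the six rating scales (excited, positive, calm, anxious, negative,
sad). `indscal()` converts `1 - r` to scalar products by Torgerson double
centring and fits the weighted-Euclidean model `B_i ~ X W_i X'` by
alternating least squares: exact nonnegative weight updates per subject
(active-set enumeration in the small dimension count) and a line-searched
configuration update, which together make the loss - and hence the reported
stress, `sqrt(SSE / sum ||B_i||^2)` - provably nonincreasing. Initialization
is classical MDS of the mean matrix; restarts are seed-governed. INDSCAL
axes are not rotation-invariant, so dimensions are reported as returned and
any alignment to a reference happens only in tests, by best-matching
permutation and sign.

Two properties of rating-profile correlations matter for interpretation:
they discard the overall level of a stimulus's profile, so configurations
are recovered up to per-dimension scale (absorbed by the INDSCAL weights),
and they are exactly monotone in configuration distance only when stimuli
have comparable profile norms. Parameter-recovery checks therefore use a
unit-norm ("circular") reference configuration; with varied subject weights
and noiseless ratings the group space is recovered at |r| > .99 per
dimension.

## Confirmatory cluster analyses

`cluster_mvpa()` re-decodes within each cluster per participant, selecting
the top 80% most stable voxels - stability being the mean pairwise Pearson
correlation of a voxel's 32-exemplar response profile across the three
*training* presentations - inside each fold's training partition only. The
ceiling rule `ceiling(0.8 V)` never selects fewer voxels than intended, and
cutoff ties break deterministically toward the lower voxel index. The test
suite contains a leakage probe: on pure-noise data, selecting on all four
presentations (test included) inflates accuracy by several points, while the
fold-internal selection stays at chance - which is why the selection lives
inside the folds.

`statis()` summarizes the exemplar geometry across participants whose
clusters have different voxel counts: each exemplar-by-voxel table is
column-centred and reduced to its 32x32 cross-product matrix; tables are
weighted by the first eigenvector of their RV-coefficient matrix; the
weighted compromise is eigendecomposed and factor scores are eigenvectors
scaled by the root eigenvalues. No per-table norm scaling is applied beyond
the RV weighting. `point_biserial()` then correlates factor scores with the
+/-1 design codes; the reported dimension is the one with the largest
absolute correlation, carried with its index.

## The synthetic-data generators

The generators' defaults are the study conditions the pipeline targets:
11 participants, 128 trials (4 x 32, 2x2 design), TR 2.2 s, 5 s + 7 s
trials, a 20x20x20 voxel grid with two disjoint 5x5x5 ground-truth regions
(valence and arousal), canonical double-gamma HRF (peak 5 s, undershoot
15 s, unit peak response), AR(1) voxel noise (rho = 0.3), and six motion
parameters simulated as smoothed random walks (their only role is as
nuisance regressors). Signal amplitudes are in percent of the voxel
baseline. The per-exemplar feature-component scores driving the nuisance
signal have their motion component correlated with arousal at r ~ 0.7, the
confound magnitude implied by the reference stimulus set's balance ANOVAs
(F(1,28) ~ 17-24 for seven motion parameters).

Synthetic clips are deliberately minimalist: a coloured background, a static
bright patch, a transient pixel-change process whose rate is the clip's
motion level (so lagged difference counts grow linearly with it at every
lag), and a stereo sine soundtrack. They emulate the *feature-level*
structure of naturalistic stimuli - motion differing by arousal, colour and
audio balanced - not their appearance; photorealism and affective
plausibility are non-goals. Passing tests on these data show that the
pipeline recovers what the generators plant under the stated noise model;
they do not certify performance under real scanner artifacts,
inter-subject anatomical variability, or feature distributions unlike the
emulated ones.

## Numerical choices and problem sizes

* IRLS: coefficient/linear-predictor change tolerance `1e-6` (`1e-8` for
  `fit_logistic`), cap 50 iterations; probabilities clipped away from 0/1.
* Kernel-space Newton systems are solved through the symmetric similarity
  transform (`W^1/2 K W^1/2 + lambda I`), avoiding an n^3 matrix product per
  iteration; Gram matrices are shared across permutation label sets.
* Cluster connectivity is 6-neighbour (faces), the most conservative
  standard choice; 26 is available.
* The cluster-size cutoff is the smallest size whose null exceedance
  probability is at most alpha; with fewer than 20 permutations a warning
  flags the cutoff as unstable.
* Degenerate inputs error early and name the offender: zero-variance feature
  columns, silent waveforms, constant trial patterns, zero-variance rating
  profiles, rank-deficient nuisance designs.
* Validation studies run at desk scale: decoding checks use 500-voxel
  grids; searchlight recovery uses the default 20^3 grid with the analysis
  mask restricted to a dilated envelope of the ground-truth region; the
  family-wise-error study uses a 10^3 grid, 6 participants, a 3^3
  searchlight and 100-permutation nulls, with the cutoff estimated once on
  an independent null dataset group and applied to 50 fresh null
  repetitions (the cutoff is a fixed functional of the shared null
  distribution, so this estimates the same error rate at a fraction of the
  cost of re-estimating it per repetition).

## Known limitations

* The localizer family-wise threshold is Bonferroni, a conservative,
  exactly reproducible stand-in for random-field FWE corrections.
* The audio "frequency" feature is the spectral centroid - a standard scalar
  summary, chosen because published frequency statistics rarely pin down
  their estimator; it is not asserted to equal any particular tool's output.
* The motion metric counts pixels whose grayscale change exceeds a
  threshold (default 10/255, configurable), summed over frame pairs at each
  lag; the lag set (default 25, 18, 12, 8, 5, 3, 1 frames at 25 fps) spans
  slow-drifting to fast-transient motion and is configurable.
* Whether the five feature regressors should enter at the volume level
  (HRF-convolved, as here) or as per-trial covariates on patterns is an open
  modelling choice; the volume-level form matches the generative model used
  throughout.
* INDSCAL stress definitions differ across historical implementations by
  monotone transforms; the value reported here is the normalized residual
  of the scalar-product fit and is comparable across runs of this package,
  not across packages.

## A worked example

```{r example, eval = FALSE}
design <- generate_design(seed = 1)
datasets <- generate_bold(design, grid_dim = c(10, 10, 5), effect_pct = 3,
                          nuisance_sd = 0.5, noise_sd = 1,
                          n_participants = 11, seed = 7)
patterns <- lapply(datasets, prep_patterns)

glance(cv_within(patterns[[1]], "valence", n_perm = 1000, seed = 1))
glance(cv_cross_exemplar(patterns[[1]], "valence"))
glance(cv_cross_participant(patterns, "valence"))

truth <- datasets[[1]]$ground_truth$valence_mask
mask <- searchlight_support(searchlight_support(truth, 5), 3)
sg <- searchlight_group(patterns, "valence", mask = mask, n_perm = 20,
                        seed = 2)
sg$clusters
cluster_mvpa(patterns, cluster_mask(sg$clusters, 1), "valence")
```
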