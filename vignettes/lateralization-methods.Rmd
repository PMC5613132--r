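---
title: "Measuring language lateralization from voxelwise Z maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring language lateralization from voxelwise Z maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralize)
```

## The problem

Most people produce language with their left hemisphere; a minority is
bilateral or right-dominant. Functional MRI quantifies this with a
**laterality index (LI)** computed from a subject's statistical
activation map for a language task (e.g. covert verbal fluency):
suprathreshold voxels are counted in paired left/right regions of
interest — classically Broca's area, BA 44/45 — and

$$\mathrm{LI} = 100\,\frac{L - R}{L + R},$$

where $L$ and $R$ are the counts surviving thresholding on each side.
+100 is complete left dominance, −100 complete right dominance, and
the closed band $[-33, 33]$ is read as bilateral organization.

A fixed Z cutoff makes LI notoriously threshold-dependent. The package
therefore uses an **adaptive threshold**: the mean of the top 5% of Z
values in the ROI pair is computed first, and voxels are counted above
50% of that mean. Every subject is thresholded relative to their own
maximal activation, which removes the global-scaling and outlier
sensitivity of fixed cutoffs.

`lateralize` implements this measurement chain end to end, together
with the analyses that are usually run around it: a threshold-free
classification of subjects from the spatial correlations of their
unthresholded maps, peak-of-activity localization, hemispheric extent
("diffuseness") statistics, mirror/conjunction map algebra, Welch and
Pearson inferential primitives, and a seed-based resting-state
connectivity model in which the left and right hemispheric global
signals are predictors of interest. Because public voxelwise data for
this design are not available, a first-class synthetic-data module
generates cohorts with planted ground truth against which every stage
is validated.

## The measurement chain

### Adaptive-threshold LI

`adaptive_threshold()` computes, per ROI side, the mean of the top
$\lceil 0.05\,n \rceil$ Z values (never fewer than one voxel). The
text this design follows says the mean is taken "in one of the paired
ROIs" without disambiguating which; the package default (`source =
"max"`) evaluates both sides and lets the larger mean — the dominant
side — set the threshold. This choice is mirror-symmetric (flipping
the map flips the counts exactly, so LI is antisymmetric under
`flip_x()`, a property the tests assert exactly), deterministic, and
consistent with thresholding against the individual's maximal
activation. `"left"`, `"right"` and `"union"` are available as
one-line variants for sensitivity analyses.

Counting is strictly `Z > threshold` everywhere. An ROI pair with no
positive activation is an error, never a silent NaN, and `L + R = 0`
likewise.

### Classification and handedness

`classify_laterality()` partitions $[-100, 100]$ into left-typical
($>33$), bilateral ($[-33, 33]$, closed: boundary subjects are
conservatively called bilateral), and right-atypical ($<-33$).
Edinburgh handedness scores classify as right-handed at $\ge +40$,
left-handed at $\le -40$, ambidextrous between.

### Threshold-free pattern graph

LI discards everything about a map except two counts. As an
independent check, `classify_patterns()` correlates each pair of
*unthresholded* maps inside the ROI-pair mask (Pearson, over masked
voxels), turns the subject × subject matrix into a weighted complete
graph, and maximizes weighted Newman–Girvan modularity with the
two-phase greedy (Louvain) method. Negative correlations are truncated
to zero by default — the modularity used is defined for nonnegative
weights, and how negative similarities entered the original
graph-based analysis is unstated; `negative = "shift"` maps weights to
$(r+1)/2$ instead. The resolution parameter defaults to 1 (the common
tool default), and a seed fixes the node processing order, making the
partition deterministic. `partition_agreement()` scores a partition
against reference labels by optimal one-to-one matching on the
confusion matrix (exact assignment search up to 8 classes).

### Peaks, extent, and map algebra

`find_peak()` returns the ROI voxel with the highest Z (ties broken by
smallest linear index); peak coordinates are compared between groups
along a world-mm axis with a Welch test (`compare_peak_axis()`), since
published peaks are reported in MNI mm. `hemispheric_extent()` re-runs
the adaptive threshold on whole-hemisphere masks and counts surviving
voxels per hemisphere — the diffuseness measure whose negative
correlation with $|\mathrm{LI}|$ expresses "more bilateral, more
tissue recruited". `flip_x()` mirrors a map by reversing the grid's
first axis with the affine untouched; this equals a world-space mirror
exactly when the x = 0 plane bisects the grid, which all synthetic
grids here guarantee (even first dimension), avoiding any resampling.
`conjunction_min()` is the minimum-statistic conjunction.
`label_clusters()` provides 26-connectivity component labeling with a
plain extent filter; it is bookkeeping plumbing, not a random-field
clusterwise correction (out of scope here), so published
GRF-derived critical cluster sizes are not reproduced.

### Inferential primitives

`welch_t_from_summary()` computes Welch's t from printed group
summaries; the statistic is second-group-minus-first throughout the
package, so calling with (typical, atypical) in that order reproduces
reported signs. `welch_t_from_samples()` is the same computation from
raw samples (and matches `stats::t.test` to 1e-10 in the tests);
`pearson_with_df()` wraps the Pearson test with its $n-2$ degrees of
freedom; `two_sample_t_map()` vectorizes the Welch statistic over
voxels and is tested against the scalar path voxel by voxel. No
multiple-testing correction is applied to t maps by default; the
extent filter of `label_clusters()` is the provided surrogate.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a 63-subject
verbal-fluency cohort on a 64 × 64 × 35 grid at 2 mm (the group EPI
grid; x and y centered on zero so the midline bisects the lattice).
Each subject receives:

* **Paired Gaussian blobs** (σ = 5 mm) inside mirror-symmetric toy
  BA 44/45 box ROIs (2040 voxels per side at 2 mm, close to a
  probabilistic cytoarchitectonic mask). The dominant-side peak is
  Z = 8; the other side's amplitude is solved by bisection so that the
  **expected** suprathreshold count ratio under the specified noise level
  realizes the planted LI (expected counts are Gaussian exceedance
  probabilities against a Monte-Carlo estimate of the expected
  adaptive threshold). With zero noise this degenerates to exact
  counts on the noiseless blob, so one-sided maps recover LI = ±100
  exactly. Planted |LI| beyond the noise-limited maximum (background
  noise keeps the silent side's expected count positive) saturates at
  that maximum; the truth table records the achieved value, and
  interior targets that cannot be matched raise an error rather than
  clipping silently. Blob centers get a seeded ±1 mm jitter —
  anatomical variability that also breaks degenerate lattice shells
  which would otherwise quantize achievable LIs coarsely.
* **Group-specific blob locations.** Typical subjects activate at
  z = 26 mm, atypical (bilateral and right-dominant) subjects at
  z = 12 mm, same x and y. This single choice plants three observed
  phenomena at once: unthresholded patterns fall into two blocks
  (within-group correlation ≈ 0.55–0.8, between ≈ −0.1 at the
  defaults), peak z coordinates differ by group while y does not, and
  the pattern-graph stage can match the LI classes exactly.
* **A diffuse hemispheric component** (peak Z = 6, σ = 20 mm,
  posterior to the ROIs, on the dominant side) whose σ scales with
  the extent multiplier $1 + \kappa(1 - |\mathrm{LI}|/100)$,
  $\kappa = 1.5$ by default, cube-rooted so the multiplier acts on
  suprathreshold volume. A log-normal between-subject σ jitter
  (sd 0.04) models recruitment variability that is independent of
  laterality; it is what makes the κ = 0 control genuinely null
  (without it, second-blob counts and threshold side effects leave a
  residual correlation of either sign).
* **White Gaussian noise** (sd 1 Z unit). The maps are "statistical"
  already, so no spatial autocorrelation is imposed by default;
  `gaussian_smooth()` can be applied to the noise field when smoother
  maps are wanted.

Planted LIs are drawn per class (truncated normals: typical
N(92, 13) on [45, 100], bilateral N(0, 12) on [−24, 24], right
N(−88, 8) on [−100, −45]) with class proportions 0.83/0.09/0.08.
Edinburgh scores enrich left/ambidextrous handedness in the atypical
classes. Everything derives from one integer seed, bit-reproducibly,
and no analysis stage ever reads the truth table.

**What passing tests show, and what they do not.** The generator
plants clean two-block pattern structure, unimodal within-class LI
distributions, and white background noise. Real Z maps have spatially
autocorrelated noise, anatomical variability far beyond a ±1 mm
jitter, within-group pattern heterogeneity (temporal-lobe recruitment
especially), and registration error. Recovery of planted truth here
validates the *implementation* of the estimators and the internal
consistency of the chain — not the field validity of LI itself.

## The resting-state stage

`simulate_resting()` builds 4-D runs (default 20 × 20 × 12 at 4 mm,
180 volumes at TR 2 s — six minutes) containing band-limited seed
signals in 5 mm spheres coupled to remote Gaussian targets with a
planted β, hemisphere-wide band-limited global components over gray
matter, Friston-style motion-correlated nuisance with a T × 6 motion
random walk, CSF/WM tissue signals, and white noise.

One generator subtlety is worth recording: a hemispheric global
component that differs between groups *only in amplitude* is
undetectable in regression betas, because the hemispheric-mean
predictor is extracted from the data itself and absorbs any scale.
The detectable asymmetry is therefore planted as **contralateral
coupling** — the dominant hemisphere's global signal also drives a
Gaussian patch (amplitude 0.5, σ = 8 mm) in the opposite hemisphere,
mirrored between groups. Group contrasts of the per-subject
$\beta_{\mathrm{gl,L}} - \beta_{\mathrm{gl,R}}$ maps then localize at
the planted patches, which the tests assert.

Processing follows the standard chain: `bandpass()` is a hard DFT
window (bins with $0.01 < |f| < 0.1$ Hz retained, DC zeroed, no
taper — exactly testable against DFT bin arithmetic),
`expand_motion_regressors()` forms the 24 motion waveforms
([m, m², lag-1 m, lag-1 m²] per parameter, first lag row zero),
`build_nuisance_design()` adds CSF and WM means with their backward
differences (28 columns; whole-brain global signal deliberately *not*
removed), `nuisance_regress()` is voxelwise OLS with residuals
orthogonal to every confound, and `seed_connectivity()` fits
[intercept | seeds | global L | global R] per voxel, returning β and
t maps plus the L−R contrast and its exact negation. Because data and
regressors are band-passed identically, filtering does not reintroduce
removed variance. Subject-level fits are OLS (no prewhitening); with
band-limited signals and white noise this is the correct small-scale
model, and the group stage works on contrast maps as usual.

## Numerical choices and degenerate inputs

* Top-5% voxel count is $\lceil 0.05 n\rceil$ with a floor of one
  voxel, so small ROIs never yield empty sets.
* Suprathreshold is strictly `>` everywhere; boundary values never
  count.
* `gaussian_smooth()` uses normalized separable convolution
  (σ = FWHM/2.355 per axis in mm), so constants are exactly preserved
  and interior blob mass to well within 1%.
* Cluster labels are renumbered by descending size with ties broken by
  discovery order; peak ties by smallest linear index.
* `two_sample_t_map()` zeroes voxels with zero variance in both groups
  and reports their count as an attribute.
* Degenerate cohorts degrade gracefully: fewer than three subjects
  skips the graph stage with a warning; fewer than two usable peaks
  per group skips the coordinate comparison.
* All replicated stochastic checks in the test suite run 63-subject
  cohorts at a reduced 44 × 44 × 24 / 3 mm resolution (the package's
  replicate-resolution choice; single-cohort checks use the full
  default grid). At 3 mm the integer-count quantization of achievable
  LIs is ≈ 2–4 units, which the planted-value samplers keep clear of
  the ±33 class boundaries.

## Worked example

```{r example, eval = FALSE}
library(lateralize)

spec <- cohort_spec(seed = 7)          # 63 subjects, 2 mm grid
cohort <- simulate_cohort(spec)
rois <- make_roi_pair(spec)

tab <- cohort_laterality(cohort$maps, rois, meta = cohort$meta)
table(tab$label)

mask <- roi_mask(rois$left$data | rois$right$data, label = "broca")
cls <- classify_patterns(cohort$maps, mask, seed = 11)
cls$partition

ext <- vapply(cohort$maps, function(m)
  hemispheric_extent(m, make_hemisphere_masks(spec))$total, 0)
pearson_with_df(abs(tab$li), ext)
```

## Known limitations

* The toy ROIs are boxes, not cytoarchitectonic probability maps; only
  their size and mirror symmetry are matched.
* No GRF clusterwise correction, surface rendering, registration, or
  task GLM fitting: synthetic Z maps stand in for first-level output.
* The LI saturates a few units short of ±100 under noise (see above);
  analyses near the endpoints should read the truth table's achieved
  values.
* OLS (not prewhitened GLS) at the subject level of the resting stage.
* The bootstrap/histogram LI family is intentionally out of scope; the
  adaptive-threshold estimator is the implemented method.
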