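---
title: "Multimodal fatigue detection: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fatigue detection: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the per-domain feature models, the fusion rule, the
numerical choices, what the synthetic generators do and do not emulate,
and where the design was genuinely open.

## The detection problem

Sleep deprivation degrades alertness in ways that show up
simultaneously in several nonintrusive channels: blink behaviour slows
and closures lengthen; the periorbital skin region warms relative to
the rest of the face; typing becomes slower and more error-prone; and
speech drops in pitch and stretches out.  The package treats fatigue
detection as a binary classification of a subject from four
simultaneously recorded modalities, fused at the score level rather
than the feature level, so each domain can be extracted, inspected and
weighted on its own.

## Visual domain

Frames are reduced to an eye-pair region of interest — either supplied
explicitly (every synthetic fixture records its true box) or found by a
pluggable detector; the built-in one thresholds the frame by Otsu's
method and takes the bounding box of the bright sclera mask.  The ROI
is histogram-equalized with the cumulative mapping
$s = 255 \sum_{j \le r} n_j / n$, which is monotone and
contrast-normalizing, then processed with a disk structuring element
(radius 2 px by default, matching the pupil scale of the templates):
grayscale opening then closing act as a speck-removing filter, a
dilation follows, and the difference between the dilated and filtered
image, binarized by Otsu's threshold, leaves the salient edges.

The eye-state decision reads the pixel profile along the ROI mid-row
and counts 0/1 transitions, with implicit zero padding at both ends so
a run touching the border still contributes two edges.  An open eye
pair crosses the profile with the edges of two sclera blobs, two
pupils, and the nose ridge; closed eyes leave only the nose, i.e. two
transitions.  The open/closed cut defaults to 6 transitions — the
midpoint between the two regimes (8+ for open, 2 for closed) — and is
configurable.  On the synthetic templates at the default noise level
the two regimes measure 18–20 versus ~4 transitions, so the decision
has a wide margin.

Blink dynamics are run-length statistics of the state series, reported
in seconds (frames divided by fps).  Two conventions were open and are
fixed as follows: ICFC counts changeover *frames* (each state change
contributes one frame), and OCOP/COCP are *mean* changeover durations.
In a strictly binary per-frame series every changeover spans exactly
one inter-frame interval, so OCOP and COCP are 1/fps whenever the
corresponding changeover occurs at all; the discriminative temporal
information is carried by ECP, ICFC and BKC.  TCT = OCOP + COCP holds
exactly by construction.

## Thermal domain

The facial pixel count uses a fixed binarization threshold of 128 on
the 8-bit grayscale image (the synthetic generator calibrates its
output against this same fixed cut; an adaptive Otsu cut is available
as an option).  ROI geometry follows the resize-and-reuse-coordinates
scheme: the visible-spectrum eye box is scaled by the ratio of image
sizes to give the periorbital box, and an identical box is stacked
directly above it (clamped at the top edge) for the forehead.

Texture is summarized from the centred power spectrum
$|F(u,v)|^2 = F \cdot F^*$.  Off-DC bins within radius $R_0$ (default:
half the smaller ROI dimension) are assigned wholly — by bin centre,
with no interpolation — to one of 16 equal-width rings and one of 16
equal wedges over $[0, \pi)$, the opposite half-plane being folded in
by conjugate symmetry.  Ring sums describe radial frequency content;
wedge sums describe orientation.  The two scalar features are the
profile totals, and because rings and wedges partition the same disc
they are both exactly the total off-DC power within $R_0$ — an
identity the tests exploit as an oracle.  The DC bin is excluded so
brightness cannot masquerade as texture, which also makes the features
invariant to constant offsets.  One numerical subtlety: wedge angles
are computed from frequency offsets normalized by the ROI dimensions
(cycles per pixel), not raw bin offsets, so an oriented texture lands
in the correct wedge even when the ROI is not square; radii stay in
bin units so $R_0$ keeps its pixel meaning.

## Keystroke domain

Logs are CSV event streams (`timestamp_ms,kind,key`).  The typed
string is replayed from press events with backspace removing the last
character; KSR still counts every press including backspaces, since
corrective presses are precisely the fatigue signal.  CRE compares the
final visible string position-by-position against the target (the
shorter string padded with a sentinel), rather than by edit distance —
so an adjacent transposition costs exactly 2.  AVD is the absolute
difference of ASCII-code sums, the one reading under which character
transpositions leave the value at zero; it is tested as invariant
under arbitrary permutations of the target.  TST runs from first press
to last release; the endpoints were unspecified and this is the widest
sensible reading.  KSR is kept as a raw count per sentence rather than
a per-second rate: the prompted sentences are of near-constant length
(around 48–54 characters), so the count is the cleaner quantity.

## Vocal domain

All features come from 30 ms frames hopped every 10 ms.  A frame is
voiced when its energy exceeds `min(noise floor + 10 dB, -30 dBFS)` —
the floor being the 5th percentile of frame energies, with the
absolute cap keeping a fully voiced clip from gating itself out — and
its normalized autocorrelation peak within the 50–400 Hz lag band
exceeds 0.3.  Pitch is the median over voiced frames of the
parabolic-interpolated autocorrelation peak; restricting the search to
the speech band plus the periodicity gate prevents octave errors on
harmonic-rich signals.  The 30 ms frame still contains 1.5 periods at
50 Hz and bounds the endpointing quantization of speech duration to
one hop.  Rate of speech is voiced segments per second (gaps under
100 ms bridged) — a pause-pattern rhythm measure, not a syllable rate.
Level is reported in dBFS because no microphone calibration exists for
file input; power is the plain mean square, the finite-sample
realization of the limiting time-average $\lim_{T\to\infty}
\frac{1}{2T}\int_{-T}^{T} s(t)^2\,dt$, kept scalar so it can sit in a
fixed-length feature vector.

## Feature selection and fusion

Within each domain, features are ranked by Fisher's discrimination
ratio $(\mu_a-\mu_b)^2/(\sigma_a^2+\sigma_b^2)$ (the squared form:
non-negative and label-symmetric) and admitted greedily while their
absolute Pearson correlation with every admitted feature stays below
0.9.  Zero-variance features are dropped with a warning.

How a domain's feature vector becomes the scalar the fusion rule
weights was left open; the package uses midpoint voting: each selected
feature votes 1 when the value lies on the fatigued side of the
midpoint between the training class means (by the stored polarity),
and the score is the mean vote.  This is the simplest mechanism that
yields scores in [0, 1] compatible with the fixed 0.5 threshold, and
the scorer is a self-contained object so a calibrated (e.g. logistic)
scorer can replace it without touching the fusion layer.

Weights live on the 3-simplex and are found by exhaustive grid search
at resolution 0.01, maximizing training accuracy at the 0.5 threshold
— with one objective and three free parameters the exhaustive search
is exact and deterministic, replacing iterative goal-attainment
machinery.  Ties are broken in a fixed order: (a) larger mean
*saturating* decision margin — each subject's signed margin counts
only up to a cap of 0.25 fused-score units — then (b) smaller L2
distance from uniform weights, then (c) lexicographic.  The margin
tie-break exists because the training-accuracy plateau is typically
wide; the resolution matters.  Picking the plateau point closest to
uniform systematically understates an informative domain's weight
(with one informative domain out of four, the returned weight for it
hovers near the smallest value that still fits the training set),
while maximizing an uncapped margin does the opposite, dumping all
weight on the single best domain and discarding the ensemble benefit
of blending when several domains are informative.  The saturation
point resolves both regimes: a lone informative domain must carry
enough weight to push *every* subject a comfortable distance past the
threshold, but once all margins are saturated further concentration
buys nothing and the distance-to-uniform tie-break selects the most
blended of the remaining candidates.  The cap of 0.25 — half the
distance from the threshold to the extreme score — marks where a
subject stops being "close to the decision boundary".  When the
scores make the weights irrelevant, every candidate ties through both
margins and the uniform weights are returned.  The published
empirical weights
(0.29, 0.37, 0.16, 0.18) are available as a preset
(`preset_weights_2023()`) rather than re-derived, since they depend on
a cohort that is not distributable.  A fused score at or above 0.5 is
classified fatigued (the boundary goes to the fatigued side).

## Evaluation harness

Confusion matrices take fatigued as positive.  Cross-validation uses
seeded stratified folds (shuffle within class, deal round-robin), fits
scorers and weights on the training folds only, and reports per-fold
matrices plus the arithmetic mean accuracy to two decimals.  The
baseline comparison trains kNN (k = 5), a single decision tree, a
100-tree random forest, a radial-kernel SVM and a one-hidden-layer
(16 unit) perceptron on the same stratified 2/3 holdout split of the
z-scored 20-feature matrix; hyperparameters are fixed and recorded
because the baselines are a comparison harness, not the contribution.

## The synthetic cohort

No recordings ship with the package, so every test input is generated.
The generators reproduce the *decision-relevant structure* of each
modality, not its appearance:

* eye frames are parametric face templates (two sclera ellipses with
  pupils plus a nose ridge, or the ridge alone) with Gaussian sensor
  noise — exactly the binary run structure the profile classifier
  reads, with ~5 versus 1 bright mid-row runs;
* thermal images are a smooth radiometric blob plus an oriented
  sinusoidal grating, recentred so the fraction of pixels above the
  fixed 128 threshold equals the requested hot fraction to within the
  quantile discreteness of the image;
* typing logs draw inter-key gaps and dwells from truncated normals
  (floor 10 ms; no timing model was prescribed) and inject
  substitutions and adjacent transpositions at given rates;
* speech is a fundamental with three decaying harmonics over a low
  noise floor, gated by a silent lead-in, one mid-sentence pause, and
  a silent tail.

A cohort is balanced by construction.  Fatigue acts only on generator
parameters — never directly on features — as standardized mean shifts
(in units of the between-subject standard deviation): shorter open-eye
runs and longer closures; higher hot fraction and texture amplitude;
slower, noisier typing; lower pitch, longer speech and longer pauses.
Alert baselines (e.g. 180 ms mean inter-key gap, 190 Hz pitch, 20 %
hot fraction, ~3-frame closures at 30 fps) were fixed once at values a
physiologist would call plausible for young adults.  Since only
endpoint accuracies — not per-feature effect sizes — are published for
real cohorts, the synthetic effect sizes are free parameters: passing
tests demonstrates that the pipeline recovers injected structure, not
that it reproduces any particular human study.

Problem sizes were likewise fixed once: default clips of 450 frames at
30 fps (a 15 s stand-in for the 3-minute protocol clips — long enough
for stable run-length statistics), 3 s speech clips, one thermal image
and one 52-character sentence per subject, and cohorts of 40 subjects
for the pipeline-behaviour tests (120 by default in `cohort_spec`,
mirroring a balanced 60 + 60 study).  The fixed seeds in tests are
arbitrary labels, not tuned quantities.

What the generators do **not** emulate: photographic face appearance
(so nothing is learned about a real Viola–Jones detector beyond the
explicit-ROI path), physiological heat diffusion, keyboard hardware
timing quirks, articulatory speech, or correlated sensor failures.
Passing tests therefore validate the algorithmic chain, not
field-readiness on human data.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on 256-bin histograms; an all-constant
  edge image short-circuits to an all-zero binary mask.
* Equalization maps through the empirical CDF and rescales to
  [0, 255]; a constant image stays constant.
* The fused-score boundary 0.5 is classified fatigued.
* `FDR` returns 0 for identical constant classes and infinity for
  separated constant classes; zero-variance features never reach the
  scorer.
* Pitch returns `NA` (unvoiced) when no frame passes the gate; the
  scorer treats missing values as neutral 0.5 votes.
* The simplex grid at resolution 0.01 has 176,851 points; accuracy is
  evaluated in vectorized chunks, and the brute-force enumeration
  oracle in the tests checks exact agreement at resolution 0.05.
* Stacked (multi-frame) morphology is an exact batch replay of the
  single-frame pipeline, asserted identical in the tests.

## Known limitations

The domain scorer is a voting heuristic: scores are coarse (multiples
of 1/k for k selected features) and uncalibrated.  OCOP/COCP are
near-constant on binary series, so four of the six visual features do
the discriminating.  Weight optimization maximizes raw training
accuracy and can overfit small cohorts — visible in the null-cohort
tests, where training accuracy is well above 50 % while held-out
accuracy stays at chance.  The thermal model carries no radiometric
calibration.  None of the synthetic results transfer claims to human
subjects.
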