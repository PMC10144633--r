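# mmfatigue

Nonintrusive detection of sleep-deprivation fatigue by late fusion of
four behavioural and physiological domains:

* **Visual** — blink dynamics from webcam frame sequences.  An
  eye-pair region of interest is histogram-equalized, smoothed by
  grayscale opening/closing with a disk structuring element, dilated,
  and reduced to a binary edge image; counting intensity transitions
  along the ROI mid-row separates open eyes (many edges from sclera,
  pupils and nose) from closed eyes (nose boundaries only, two edges).
  Run-length statistics of the per-frame open/closed series give six
  features: total closed time (ECP), the open-to-closed and
  closed-to-open changeover periods (OCOP, COCP), their sum (TCT), the
  changeover-frame count (ICFC) and the blink count (BKC).
* **Thermal** — the white-pixel count of the binarized facial image
  plus Fourier power-spectrum texture sums.  The eye-pair box is mapped
  onto the 320x240 thermal image to give the periorbital ROI, with an
  identical box stacked above it for the forehead.  Each ROI's centred
  power spectrum `|F(u,v)|^2` is partitioned into concentric rings and
  angular wedges; the ring and wedge profile sums give the radial and
  angular texture features (FHFa, FHFr, PRFa, PRFr).
* **Keystroke** — from a prompted-sentence typing log: keypress count
  (KSR), position-wise character errors (CRE), the absolute difference
  of ASCII-code sums between typed and target text (AVD, zero under
  character transpositions), and first-press-to-last-release time
  (TST).
* **Vocal** — from a mono clip: autocorrelation pitch restricted to
  50-400 Hz (FFP), voiced-segment rate (RSH), level in dBFS (SPL),
  mean-square power (PSD), and energy-endpointed speech duration
  (SPD).

Per-domain features are reduced by Fisher's discrimination ratio
`FDR = (mu_a - mu_b)^2 / (sigma_a^2 + sigma_b^2)` with a correlation
cap, converted to a score in [0, 1] by midpoint voting, and fused as

    fused = alpha * visual + beta * thermal + gamma * keystroke + delta * vocal

with non-negative weights summing to one, found by exhaustive simplex
grid search maximizing training accuracy; a subject is called fatigued
when the fused score reaches 0.5.  The package also ships synthetic
generators for all four modalities with controllable fatigue effect
sizes, a stratified k-fold evaluation harness, five baseline
classifiers (kNN, decision tree, random forest, SVM, MLP), and a CLI.

## Worked example

```r
library(mmfatigue)

spec <- cohort_spec(n_subjects = 40,
                    effect_sizes = c(visual = 3, thermal = 3,
                                     keystroke = 3, vocal = 3),
                    seed = 1)
cohort <- generate_cohort(spec)        # renders + extracts all domains
model <- fit_fusion_model(cohort)
round(unclass(model$weights), 2)
#> alpha  beta gamma delta
#>  0.25  0.25  0.00  0.50
model$training_accuracy
#> [1] 100
kfold_cv(cohort, k = 3, seed = 1)
#> Stratified 3 fold cross-validation
#>   fold 1: TP=7 FN=0 FP=0 TN=7  accuracy 100.00%
#>   fold 2: TP=7 FN=0 FP=0 TN=7  accuracy 100.00%
#>   fold 3: TP=6 FN=0 FP=0 TN=6  accuracy 100.00%
#>   average accuracy 100.00%
```

With all four effect sizes at 3 between-subject standard deviations the
cohort is separable by construction, so the fitted weights achieve
perfect training accuracy and cross-validation stays at or near 100%;
with effect sizes at 0 the same pipeline hovers around 50%.

The command line mirrors the same flow:

```sh
Rscript inst/scripts/mmfatigue.R simulate --out fixtures --n 12 \
        --effects 3,3,3,3 --seed 5
Rscript inst/scripts/mmfatigue.R extract-all \
        --manifest fixtures/manifest.yaml --out features.csv
Rscript inst/scripts/mmfatigue.R fit --features features.csv --out model.json
Rscript inst/scripts/mmfatigue.R evaluate --features features.csv --k 3
```

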