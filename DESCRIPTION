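Package: mmfatigue
Title: Multimodal Detection of Sleep-Deprivation Fatigue from Visual,
    Thermal, Keystroke and Vocal Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A nonintrusive pipeline for detecting sleep-deprivation
    fatigue by late fusion of four behavioural and physiological domains:
    blink dynamics extracted from webcam frame sequences with an
    image-profile eye-state classifier, Fourier power-spectrum ring/wedge
    texture features from periorbital and forehead regions of thermal
    images, keystroke-dynamics features from prompted-sentence typing
    logs, and pitch/energy features from short speech clips.  Per-domain
    feature vectors are reduced by Fisher's discrimination ratio, turned
    into scores in [0, 1], and fused with non-negative simplex weights
    optimized by exhaustive grid search; a 0.5 threshold separates alert
    from fatigued subjects.  Includes synthetic generators for all four
    modalities with controllable effect sizes, a stratified k-fold
    evaluation harness with baseline classifier comparisons, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    e1071,
    jsonlite,
    nnet,
    png,
    randomForest,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
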