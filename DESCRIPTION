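Package: MRFOpt
Title: Manta-Ray Foraging Optimization of Transfer-Learning Hyperparameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the manta-ray foraging optimization (MRFO) swarm
    metaheuristic for tuning transfer-learning image classifiers over a
    15-element encoded hyperparameter space (loss, batch size, dropout,
    layer-freezing ratio, optimizer, per-image scaler, and a data
    augmentation policy). Ships the accompanying preprocessing stack
    (bicubic resizing, four per-image dimensional scalers,
    augmentation-based class balancing, stratified double splitting), a
    pluggable fitness interface with a small trainable network backbone
    and analytic test objectives, a confusion-matrix metric suite
    (accuracy, precision, specificity, recall, Dice, F1 with micro
    aggregation for multiclass), and a synthetic textured image generator
    for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
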