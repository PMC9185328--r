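Package: gtotune
Title: Gorilla Troops Optimizer Hyperparameter Search for Transfer-Learning
    Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metaheuristic hyperparameter optimization for convolutional
    image classifiers using the Artificial Gorilla Troops Optimizer (GTO).
    Candidate configurations are encoded as vectors in the unit hypercube and
    decoded through an ordered search space covering loss function, batch
    size, dropout, fine-tuning (layer-unfreezing) ratio, weight optimizer,
    image scaling technique and a full set of data-augmentation parameters.
    Includes the supporting pipeline for brain-MRI-style image data:
    signal-to-noise based cleaning, bicubic resizing, category encoding,
    four image scaling techniques, stratified splitting, augmentation-based
    class balancing, a micro-averaged multi-class confusion-metrics suite,
    a CPU-trainable toy network fitness harness, and a seeded synthetic
    brain-image generator so the whole loop is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pROC,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
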