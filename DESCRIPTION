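Package: p3msda
Title: Multi-Source Adversarial Domain Adaptation for Single-Trial P300 Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised multi-source domain adaptation for cross-subject
    single-trial detection of P300/oddball EEG responses. Labeled subjects are
    screened by clustering their P3 scalp topographies into strong, medium and
    weak groups; strong-response subjects form the source domains. A compact
    convolutional feature extractor is trained adversarially against per-source
    domain discriminators through a gradient reversal layer, per-source category
    classifiers are combined by perplexity-derived weights, and target samples
    are re-ranked by ensemble probability each epoch so that the rare deviant
    class is not swamped during training. Includes a seeded multi-subject
    event-related-potential simulator so every stage can be exercised and tested
    without access to raw EEG recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
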