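Package: dfunet
Title: Dual-Track Swin Transformer and Multi-Scale Attention Networks for
    Diabetic Foot Ulcer Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dual-track deep network for classifying diabetic
    foot ulcer (DFU) photographs into four complication classes (none,
    infection, ischemia, both). One track is a hierarchical shifted-window
    (Swin) transformer; the other is an efficient multi-scale
    attention-driven CNN (EMADN) built from lightweight multi-scale
    deformable shuffle (LMDS) blocks and global dilated attention (GDA)
    blocks. Track features are fused, refined by shuffle attention, and
    classified through a pooled ReLU head. The package ships its own
    compact tape-based reverse-mode automatic differentiation engine and
    layer library, Grad-CAM saliency maps, a seeded synthetic four-class
    image generator with the study's split and minority-class augmentation
    bookkeeping, a training loop with SGD + momentum and step decay, a
    grid-search harness, and multi-class evaluation metrics with one-vs-rest
    ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
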