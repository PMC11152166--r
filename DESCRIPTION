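Package: devevent
Title: Developmental Event Detection from Embryo Time-Lapse Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the onset of developmental events in
    embryo time-lapse video. Implements a compact (2+1)D residual
    convolutional video classifier trained on hourly clips, selective
    data augmentation for class-imbalanced clip datasets, probability
    trajectory construction and peak/threshold event-onset extraction,
    metric-learning embeddings of developmental trajectories, and
    treatment-level summaries of thermal plasticity in developmental
    rate. Includes a deterministic synthetic embryo video generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
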