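Package: woundtissue
Title: Chronic Wound Tissue Segmentation and Classification from RGB
    Photographs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated assessment of chronic-wound photographs. Segments
    the wound bed from an RGB image by fuzzy-divergence threshold
    selection on the HSI saturation channel, extracts a 675-entry color
    and texture descriptor (moments, entropy, local contrast and
    rotation-invariant local binary patterns over 45 color channels) per
    tissue region, ranks features by one-way F statistic, and classifies
    regions as granulation, slough or necrotic tissue with naive-Bayes
    and kernel support-vector learners. Includes a synthetic wound-image
    generator with ground-truth masks so the full pipeline is testable
    without clinical images, and evaluation utilities (confusion
    matrices, tissue-wise and overall accuracies, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'classification.R'
    'color-model.R'
    'evaluation.R'
    'features.R'
    'imaging-io.R'
    'pipeline.R'
    'segmentation.R'
    'selection.R'
    'synthetic.R'
    'woundtissue-package.R'
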