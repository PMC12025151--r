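Package: UBMbiometry
Title: Anterior-Segment Biometry and Angle-Closure Mechanism Assessment
    from Labeled Ultrasound-Biomicroscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures angle-closure biometry on tissue-labeled
    ultrasound-biomicroscopy (UBM) anterior-segment images and classifies
    the closure mechanism of each single-angle image. Provides
    physical-coordinate handling for the half-frame and panorama
    acquisition geometries, automatic scleral-spur localization, circle
    intersection iris-thickness measurement, iris curvature and root
    insertion metrics, iris-ciliary body contact-ratio measurement, a bank
    of five binary classifiers with Matthews-correlation-first model
    selection, a rule-based four-way integrated assessment (pure pupillary
    block, pure non-pupillary-block, multiple mechanisms, others), the full
    set of evaluation statistics, and a parametric synthetic
    anterior-segment renderer with analytic ground truth for end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    yaml,
    EBImage,
    randomForest,
    e1071,
    xgboost,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
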