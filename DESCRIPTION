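Package: spinefate
Title: Functional Predictors of Dendritic Spine Elimination During Motor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal two-photon imaging of dendritic
    spine glutamate and dendritic calcium during a cued lever-press task. Takes
    lever displacement traces and per-ROI fluorescence time series to movement
    bouts, dF/F0 event trains, movement-related spine classification by
    permutation, distance-binned spine co-activity and co-activity environment
    scores, label-shuffle spatial clustering tests, spine-dendrite event onset
    timing, and linear mixed-effects group comparisons. Includes a seeded
    synthetic-session generator with ground truth so every stage is testable
    without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    minpack.lm,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
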