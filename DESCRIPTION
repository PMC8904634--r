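Package: celiascope
Title: Capsule-Endoscopy Frame Analysis for Computer-Aided Celiac Disease Screening
Version: 1.0.0
Authors@R:
    person("celiascope", "developers", email = "celiascope@example.org",
           role = c("aut", "cre"))
Description: Image-processing and classification pipeline for small-bowel
    capsule-endoscopy frames aimed at celiac disease screening. Frames are
    cleaned (overlay-text removal by border-band region filtering, black-border
    cropping), passed through a bespoke filter bank (contrast-windowed Sobel
    edge magnitude, a hand-designed 3x3 crack-detection kernel), and reduced to
    ten per-frame descriptors (intensity and RGB statistics, edge and crack
    pixel sums, histogram entropy, large/small region counts). Per-video
    summaries feed three lightweight classifiers: 3-nearest-neighbour,
    inverse-distance-weighted 3-NN, and a linear hinge-loss support vector
    machine with balanced class weights. A seeded synthetic frame generator
    emulates the relevant mucosal phenotypes so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    jpeg,
    png,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
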