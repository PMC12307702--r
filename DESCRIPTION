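Package: ki67match
Title: Cell-Level Evaluation of Automated Ki67 Nucleus Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing automated Ki67 nucleus-detection outputs
    against a pathologist reference standard at the level of individual
    cells. Dot annotations from reference and detector are mapped onto a
    common coordinate grid, paired by distance-capped optimal one-to-one
    assignment, and summarised as true-positive, false-positive and
    false-negative detections with false discovery rate, precision,
    recall and F-score. Ki67 proliferation scores are computed per region
    of interest and per case with WHO G1/G2/G3 grade assignment, and
    agreement between detector and reference is quantified with the
    two-way mixed single-measures intraclass correlation coefficient,
    nonparametric Bland-Altman limits of agreement and the paired
    Wilcoxon signed-rank test. A seeded synthetic-data generator produces
    reference annotation sets and detector outputs with configurable
    error modes (localisation jitter, class-specific misses, clutter,
    split and merged cells, label flips) so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
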