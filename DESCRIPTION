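Package: recruitnet
Title: Time-Resolved AP-MS Interactor Detection and Co-Recruitment Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of time-resolved affinity-purification mass-spectrometry
    (AP-MS) experiments that profile a tagged bait against matched wild-type
    controls over a stimulation time course. Detects specific interaction
    partners from label-free protein intensities using per-time-point
    enrichment and one-way ANOVA stabilised by bootstrap resampling, imputes
    missing values from the control-background intensity model, builds
    bait-normalized recruitment kinetics, infers a co-recruitment correlation
    network with bootstrap Pearson statistics under a Bonferroni edge
    threshold, and benchmarks predicted protein-protein interactions against a
    reference interaction list. Includes a synthetic-data generator with
    planted interactors, kinetic modules, contaminants and intensity-dependent
    missingness so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
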