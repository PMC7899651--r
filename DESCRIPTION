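Package: perifreeze
Title: Peri-Event Spike-Train Analysis for Fear-Conditioning Sessions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-unit spike trains recorded during
    Pavlovian fear-conditioning and retrieval sessions. Builds validated
    session timelines for partially and fully reinforced conditioning
    protocols, scores freezing behaviour from bout intervals, aligns spikes
    to conditioned-stimulus and freezing onset/cessation events, z-normalises
    peri-event histograms to a pre-event baseline, classifies units as
    CS-ON, Freeze-ON or Freeze-OFF by a fixed threshold-crossing rule, and
    compares responsive-unit proportions across groups with exact tests.
    Includes a seeded synthetic-data generator (inhomogeneous Poisson spike
    trains with event-locked rate modulation and a two-state freeze/move
    behaviour model) so every stage of the pipeline can be verified against
    ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
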