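Package: wormsleep
Title: Quantification of Sleep, Olfactory Memory, and Synaptic Dynamics in
    C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Caenorhabditis elegans sleep and
    odor-memory experiments: quiescent-bout detection from pixel-displacement
    video time series (9-frame rule at 3 s/frame), raster and hourly
    quiescence summaries, 17-point skeleton posture and locomotion metrics
    (midpoint bending angle, centroid speed, stillest-window selection),
    chemotaxis and learning index scoring with trial censoring and
    imaging-batch behavioral gates, GCaMP delta-F/F0 response magnitudes,
    transsynaptic-marker punctal intensity quantification with same-day
    reference normalization, and a square-root-scale piecewise-linear
    (knotted) regression of the synaptic time course with a slope-change
    test.  Includes a seeded synthetic-data generator (two-state Markov
    displacement dynamics, multinomial plate counts, correlated
    sleep-memory trial pairs, hinge-basis synaptic means, parametric
    skeletons) so every stage is testable without raw video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
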