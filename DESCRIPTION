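Package: remoterep
Title: Closed-Loop Hippocampal Neurofeedback Analysis on Synthetic Place-Cell Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for simulating and analysing closed-loop hippocampal
    neurofeedback experiments on a Y-maze. Implements clusterless marked
    point-process decoding of linearized position in 6 ms bins, the
    remote-representation trigger criteria (posterior-mass thresholds,
    tetrode spatial specificity, port proximity), head-direction feedback
    with a tightening angular tolerance, classification of detected events
    into jump and trajectory categories, a target-representation prevalence
    statistic with rank-sum and longitudinal-trend inference, PCA/ICA
    cell-assembly detection with Marchenko-Pastur significance and
    zero-diagonal activation strength, sharp-wave-ripple detection and
    theta-phase brain-state segmentation, and a synthetic session generator
    with ground-truth event injection so the whole pipeline is testable
    end-to-end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
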