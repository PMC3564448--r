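Package: episodecode
Title: Place-Field Remapping and Ensemble Trajectory Decoding on a
    Figure-Eight Maze Task
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of hippocampal episodic coding on a
    figure-eight maze task with visually guided, spatial-alternation and
    delayed-alternation subtasks. Provides a synthetic session generator
    (lap schedule, 60 Hz virtual-rat tracking, inhomogeneous-Poisson place
    cells with configurable global and rate remapping), path linearization
    and behavioral covariates, occupancy-normalized kernel rate maps with
    Skaggs spatial information, spatial and rate similarity indices, an
    ANCOVA screen for differential firing, and state-space ensemble
    trajectory classification (leave-one-out nearest-mean-template
    decoding, permutation nulls, cross-subtask generalization, cell-count
    curves and PCA visualization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'taskmodel.R'
    'behavior.R'
    'stats.R'
    'placefields.R'
    'ensemble.R'
    'cli_io.R'
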