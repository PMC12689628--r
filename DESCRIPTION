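Package: sleepedit
Title: Vigilance-State EEG Spectral Analysis, Prime-Editing Quantification,
    and 3D Plaque Phenotyping for Brain Genome-Editing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for studies that install a genetic variant
    in the mouse brain by prime editing and phenotype the animals by
    EEG/EMG sleep recording, open-field behaviour, deep amplicon
    sequencing, and cleared-hemisphere light-sheet imaging.  Implements
    4-s-epoch Welch spectral analysis with a hybrid 0.5/1 Hz binning
    scheme, rule-based vigilance-state scoring, cross-state and
    within-state spectral normalization, slow-wave-activity timecourses,
    amplicon read classification with editing and indel rates,
    sliding-window locomotion kinematics with running-episode detection,
    probability-volume plaque segmentation with 26-connectivity and
    microglia colocalization, and Pearson correlation of editing
    efficiency against phenotypes.  Every analysis is exercisable on
    synthetic data produced by the package's own generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    Biostrings,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
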