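Package: eegmicrostates
Title: Electrical Neuroimaging of Event-Related EEG: Microstate Segmentation and Distributed Source Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of high-density event-related EEG in the
    electrical neuroimaging tradition. Provides a seeded synthetic-data
    generator for multi-subject, multi-condition visual evoked potential (VEP)
    studies with a known microstate schedule and dipolar generators; first-level
    preprocessing (amplitude-threshold epoch rejection, spherical-spline channel
    interpolation, averaging, baseline correction, zero-phase band-pass
    filtering, average referencing, mean-GFP normalization); second-level
    topographic microstate segmentation by atomize-and-agglomerate hierarchical
    clustering with a modified Krzanowski-Lai model-selection criterion;
    back-fitting of group templates to single-subject VEPs with
    repeated-measures ANOVA on microstate durations; and a LORETA-style
    distributed inverse solution on a gridded three-shell spherical head model
    with paired-t cluster-extent contrasts between microstate time windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    Matrix,
    jsonlite,
    yaml,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
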