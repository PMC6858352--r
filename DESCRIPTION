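Package: duvmap
Title: Patch-Based Metastasis Mapping for Deep-UV Excitation Fluorescence
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-image detection of lymph node metastasis in
    deep-UV excitation fluorescence microscopy frames. Provides a synthetic
    fluorescence-histology generator with ground-truth tumor masks, a
    278x278 patch extraction and labeling pipeline with leakage-free
    node-grouped splits, a pluggable patch classifier contract (including a
    trainable small CNN and a seeded noisy oracle), mirror-padded
    sliding-window dense prediction mapping, majority-decision map
    smoothing with per-step vote windows, threshold-sweep evaluation
    tables, overlay rendering, and a command-line driver for end-to-end
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
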