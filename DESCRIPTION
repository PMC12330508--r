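Package: votcsim
Title: Simulation and Individual-Versus-Group Analysis of Category-Selective Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of cortical surface meshes carrying
    category-selective patches (a small, spatially variable text-selective
    patch and a larger, stable face-selective patch) inside a ventral
    occipitotemporal mask, generates localizer BOLD time series under
    one-back and fixation tasks, and runs the analysis chain used to
    study such regions: per-vertex GLM estimation, contrast t-maps and
    percent-signal-change maps, threshold-based ROI definition within
    anatomical limits, Dice overlap between task-specific ROIs,
    probabilistic maps and group ROIs in a common template space with a
    registration-error model, vertex-wise group t-tests, overlap-indicator
    maps, and selectivity-index comparisons between native, group, and
    template ROIs. Demonstrates how small spatially variable regions
    survive individual-level analysis but are obscured by template-space
    averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
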