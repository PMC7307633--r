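Package: apcdend
Title: Dendritic Development Analysis for Piriform Cortex Layer 2 Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing circuit-specific dendritic development of
    anterior piriform cortex layer 2 neurons: layer-aware morphometry of SWC
    neuronal reconstructions (branch decomposition, total dendritic branch
    length, termination-layer classification against traced laminar
    boundaries), population calcium-imaging event detection and
    coactivity-versus-depth analysis, current-clamp intrinsic-property and
    EPSP feature extraction, and a Poisson model of clustered synaptic input
    and dendritic NMDA-spike probability with a Monte-Carlo oracle. Includes
    seeded synthetic-data generators that emulate the statistical structure
    of each data modality so that every pipeline stage is testable end to
    end without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    tiff,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
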