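Package: punctate
Title: Quantification of Compartmentalized Fluorescence in Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the subcellular distribution of fluorescently
    tagged proteins in cultured neurons: compartment enrichment indices for
    the primary cilium and for marker-defined endosomes, puncta counting and
    population positivity classification, live-cell receptor accumulation
    kinetics at endosomes, cAMP/PKA biosensor time-course summarization
    (dF/F0, two-phase area under the curve, peak and plateau, Fsk/IBMX
    endpoint normalization), and distance-based spot-to-compartment
    colocalization. A synthetic-microscopy generator with full ground truth
    makes every stage testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    igraph,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
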