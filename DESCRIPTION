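Package: cytograd
Title: Simulation and Quantification of Cytoneme-Mediated Morphogen Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how contact-dependent transport through
    cytonemes shapes tissue-specific morphogen gradients, modelled on FGF/Bnl
    signalling from the Drosophila wing disc to the air-sac primordium (ASP).
    The package provides a deterministic/stochastic feedback simulator of
    ligand uptake on a one-dimensional chain of recipient cells, in which
    transcription-factor readouts (PntP1, Cut, Yan) feed back on receptor and
    cytoneme production; a synthetic multi-channel microscopy-scene generator
    with full ground truth; and quantification routines for gradient
    profiling (curved-epithelium straightening, band-limited intensity
    profiles, exponential fits and the Cmax-to-half-max slope statistic),
    mosaic-clone intensity ratios, punctum detection and colocalization, and
    cytoneme length/orientation/contact statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
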