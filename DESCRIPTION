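Package: fluctsort
Title: Surface-Fluctuation-Driven Sorting of Embryonic Lineages: Simulation and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how differential cell-surface fluctuations,
    rather than static adhesion or tension differences, physically sort
    epiblast (EPI) and primitive-endoderm (PrE) progenitors in the early
    mouse embryo. Provides a 3D subcellular-element cell-sorting simulator
    with Morse inter-element forces, a Delaunay cortex-tension network,
    interfacial-tension asymmetry and sinusoidal tension fluctuations;
    sorting statistics (external-surface fraction with a randomization
    null, sorting index, demixing parameter, radial enrichment); a 2D
    vertex-model energy with FIRE relaxation and self-propelled-Voronoi
    demixing dynamics; membrane-contour fluctuation quantification (polar
    resampling, detrending, temporal amplitude), shape-index utilities,
    doublet contact-angle mechanics and parallel-plate AFM tension; plus
    seeded synthetic-data generators with stored ground truth for every
    analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    jsonlite,
    deldir
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
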