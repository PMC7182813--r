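Package: adhesim
Title: Surface Energetics, Cell-Coverage Imaging, and Lipase Kinetics for
    Microbial Adhesion Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying microbial adhesion to solid surfaces.
    Decomposes sessile-drop contact angles into Lifshitz-van der Waals and
    Lewis acid-base surface-energy components of a solid via the three-liquid
    van Oss-Chaudhury-Good system, classifies surface hydrophobicity, and
    propagates contact-angle uncertainty by Monte Carlo. Quantifies the
    fraction of a surface covered by adherent cells from grayscale
    micrographs (binarization, morphological cleanup, 8-connected object
    labeling, replicate statistics), assembles factorial adhesion-assay
    tables with treatment contrasts and ionic-strength profiles, and derives
    lipase activity of free and surface-immobilized cell debris from
    p-nitrophenol absorbance kinetics. Synthetic-data generators with known
    ground truth (micrographs, contact-angle sets, kinetic traces) make
    every pipeline stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
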