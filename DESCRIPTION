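Package: rgbchem
Title: Molecular Structures as RGB Images for Convolutional Property Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes 3D molecular structures as three-channel images whose
    pixels carry chemical descriptors (interatomic distance, full or reduced
    Coulomb matrix, ReaxFF-style uncorrected bond order, first ionization
    energy, atomic number), with atom-order shuffling strategies that turn one
    molecule into many distinct training images. Ships compact one- and
    two-stage convolutional regression networks (S1CNN/S2CNN), trained with
    Adam and zero-delta early stopping, to predict scalar molecular properties
    such as the HOMO-LUMO gap, plus a synthetic QM9-like molecule generator
    and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
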