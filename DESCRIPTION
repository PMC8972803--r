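Package: globaldyn
Title: Elastic Network Models and Essential Dynamics of Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained analysis of protein global dynamics: anisotropic
    and Gaussian network model (ANM/GNM) normal mode analysis, principal
    component analysis of superposed structural ensembles (essential
    dynamics), comparative "signature dynamics" across families of related
    structures with covariance-overlap distances and UPGMA trees,
    vibrational subsystem analysis (VSA) Hessian reduction, and
    neural-gas vector quantization of cryoEM-style density maps into
    pseudoatoms for downstream normal mode analysis. Includes PDB and
    MRC2014 readers/writers, synthetic fixture generators with planted
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    pracma
Config/testthat/edition: 3
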