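Package: pepAAWS
Title: Amino-Acid-Associated Weights for Antibody Binding on Random-Peptide
    Microarrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates signal intensities of antibody mixtures binding
    random-sequence peptide microarrays via a string-vector Langmuir
    adsorption model, and estimates amino-acid-associated weights (AAWS)
    from peptide composition alone by partial least squares regression
    with cross-validated predictive performance (Q2). Includes ensemble
    analyses of antibody-repertoire diversity, noise and antibody
    dominance, principal component analysis of AAWS, and correlation of
    AAWS with user-supplied amino-acid property scales.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'aawsRegression.R'
    'bindingModel.R'
    'ensemble.R'
    'io.R'
    'pepAAWS-package.R'
    'peptideLibrary.R'
    'pls.R'
    'run.R'
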