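Package: anuromorph
Title: Phylogenetic Ecomorphometrics of Anuran Skeletal Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for size-corrected analysis of linear skeletal measurements
    across frog species on a phylogeny. Computes Mosimann log-shape variables,
    phylogenetic principal component analysis under Brownian motion, shape PCA
    in isometry-free shape space with bootstrap PCA ratio spectra and allometry
    spectra, PERMANOVA with pairwise contrasts, phylogenetic generalized least
    squares with maximum-likelihood Pagel's lambda, and linear and phylogenetic
    flexible discriminant analysis of locomotor mode, habitat and clade,
    including held-out tip prediction and case-wise reports. A synthetic-data
    generator evolves labelled trait sets on simulated trees for power and
    parameter-recovery studies, and a pipeline driver reproduces the full
    analysis surface from a configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vegan,
    MASS,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
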