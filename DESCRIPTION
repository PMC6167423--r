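Package: fingernet
Title: NMR Metabolic Fingerprinting and Metabolic Sub-Network Extraction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis chain from binned 1H-NMR metabolomics spectra of
    exposed cell cultures to modulated metabolic sub-networks. Provides
    orthogonal signal correction (OSC), NIPALS PLS-DA with cross-validated
    Q2, permutation validation and VIP scores, Kruskal-Wallis based
    discriminant-bin selection, chemical-shift annotation of discriminant
    bins into metabolic fingerprints, compartment collapsing of genome-scale
    metabolic networks read from SBML, node-weighted lightest-path
    sub-network extraction from fingerprint seeds, and set algebra on
    sub-networks to separate effects shared between two compounds from
    compound-specific effects. Includes a synthetic-spectra generator with
    planted signatures and a structured confounder for validation of the
    whole chain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    xml2,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
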