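Package: evostruct
Title: Joint Analysis of Protein Structure and Evolutionary Age as Determinants of Evolutionary Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how protein structure and evolutionary age
    jointly shape protein evolutionary rates. Implements residue-level
    solvent-accessibility and secondary-structure classification from
    DSSP-style records, phylostratigraphic age assignment from homolog
    presence/absence profiles, concatenation-based dN/dS estimation with the
    Nei-Gojobori counting method, a coarse-grained four-body knowledge-based
    stability potential built on a Delaunay tessellation of alpha-carbon
    positions, mutational-robustness simulation (Z-score and rank of the
    native sequence among mutant populations), and the statistical layer
    (binned correlations, RSA-by-age interaction models, Wilcoxon suites,
    length-binned pairing). A synthetic-data generator produces structures
    with planted hydrophobic cores, orthologous codon pairs with
    accessibility-dependent substitution rates, homolog hit tables and decoy
    sets, so the whole pipeline is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
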