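Package: ecl2scan
Title: Mutagenesis-Guided Analysis of Receptor Loop Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for combining alanine-scan pharmacology with modelled
    conformational ensembles of a G-protein-coupled receptor extracellular
    loop bound to a peptide agonist. Computes residue-residue contact maps at
    a fixed heavy-atom distance cutoff, aggregates interaction frequencies
    over an ensemble, derives functionally key residues from paired
    concentration-response data, applies criteria-based conformation
    selection (mandatory partner contacts, key-interaction counts, score
    percentiles, side-chain orientation), and screens paired multi-species
    alignments of two receptor-peptide systems for correlated substitutions.
    Includes a synthetic-data module (toy helical-bundle complex builder,
    cyclic-coordinate-descent loop sampler with a surrogate pseudo-energy,
    dose-response and alanine-scan simulators) so the full pipeline runs at
    desk scale without external modelling software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
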