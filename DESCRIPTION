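Package: genodelim
Title: Genome-Based Delineation of Bacterial Species Complexes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delineating genospecies within bacterial species
    complexes from genome assemblies. Implements fragment-based average
    nucleotide identity (ANI) with k-mer seeding and banded alignment,
    gap-based genospecies clustering with compactness refinement, a
    reference-anchored core-gene concatenated phylogeny, chromosome/plasmid
    compartment classification from marker-gene carriage, reciprocal-best-hit
    orthogrouping with a normalized gene-sharing index, and marker-based
    strain typing (16S rRNA variant profiles, nodulation-gene symbiovars,
    housekeeping-gene amplicon classification). Ships a synthetic
    species-complex simulator with full ground truth so every stage can be
    validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'genodelim-package.R'
    'classes.R'
    'seqio.R'
    'align.R'
    'search.R'
    'simulate.R'
    'ani.R'
    'genospecies.R'
    'corephylo.R'
    'compartments.R'
    'accessory.R'
    'markers.R'
    'pipeline.R'
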