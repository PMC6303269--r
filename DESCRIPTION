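Package: fadpat
Title: Pattern Analysis of the Conserved FAD-Binding Region of L-Amino
    Acid Oxidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Motif-anchored pattern analysis of the conserved 47-amino-acid
    FAD-binding region of L-amino acid oxidase (LAAO) proteins. Partitions
    the region into five sub-regions anchored on the GxGxxG FAD-binding and
    GG (RxGGRxxS/T) motifs, catalogues unique amino acid patterns per
    sub-region, encodes each sequence as a five-digit combinatorial code,
    clusters codes by agglomerative hierarchical clustering with
    deterministic tie-breaking, profiles residue and biochemical-property
    frequencies, derives consensus motif strings, classifies nucleotide
    substitutions as silent or missense under the region's reading frame,
    and scores residue-wise secondary-structure conservation on a 0-4
    scale. Includes a seeded synthetic-data generator producing
    group-structured alignments, back-translated nucleotide companions and
    beta-alpha-beta secondary-structure strings, so that every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
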