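Package: ridscape
Title: Comparative Genomics of the Rid (YjgF/YER057c/UK114) Protein Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profile-based detection and subfamily classification of Rid
    (reactive intermediate deaminase, YjgF/YER057c/UK114) family proteins,
    active-site conservation calls, tandem-fusion detection, chromosomal
    gene-neighborhood association statistics, MOTU-style genome-set
    dereplication, and phylogenetic-distribution tabulation.  Includes a
    fully labeled synthetic prokaryotic genome simulator (planted subfamily
    copies, gene-cluster partners, tandem fusions, and a controlled
    genome-size/copy-number correlation) so that every pipeline stage can be
    exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
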