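Package: rapscan
Title: Discovery Analytics for RNA-Polymerase-II-Binding Aptamers from Genomic SELEX
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genomic-SELEX screens for RNA polymerase
    II-binding aptamers (RAPs). Implements strand-aware assignment of selected
    reads to repeat families with fold-enrichment normalised to genomic
    abundance, in-silico translation of repeat DNA and global Needleman-Wunsch
    alignment (BLOSUM62, affine gaps) against the Pol II carboxy-terminal
    domain, and a codon-normalised amino-acid composition test based on the
    Jensen-Shannon divergence with a Monte-Carlo null of background-frequency
    random RNA. A synthetic-data generator emulates the SELEX experiment
    (background genome, planted repeat families including CTD-codon-like
    satellite units, affinity-weighted read selection) so that every stage is
    testable with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
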