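Package: coiaudit
Title: COI Barcode Reference-Library Auditing and Metabarcoding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing DNA barcode (COI-5P) reference libraries and for
    analysing bulk-sample metabarcoding runs against them. Implements Kimura
    2-parameter barcode-gap statistics with pairwise deletion and a 500-bp
    length filter, single-linkage haplotype clustering as a documented BIN
    proxy, neighbour-joining trees, species-discordance classification
    (cryptic-diversity candidates and cluster sharing) with severity banding,
    interim "reverse taxonomy" naming, a merge-trim-filter-dereplicate-
    dechimera-cluster-assign metabarcoding pipeline, family-level dark-taxa
    summaries with one-sided Pearson correlations, and synthetic COI data
    generators with ground truth so every stage is testable without external
    downloads. Ships transcriptions of the published family, cryptic-diversity
    and cluster-sharing tables of a large Diptera barcoding campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
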