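Package: g4screen
Title: Genome-Wide G-Quadruplex Motif Discovery and Matched-Control
    Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies intramolecular G-quadruplex (G4) motifs matching
    (G>=3 N1-25)3 G>=3 on both strands of a genome, builds resampling nulls
    from control regions matched 1:1 to motifs by chromosome, length and GC
    content, and tests motif association with annotation tracks and
    ChIP-seq peak sets (empirical P-values, Storey q-values, Fisher and
    binomial contingency statistics, paired peak-significance comparison,
    helicase-dependence motif classes, and cross-species conservation
    through pairwise alignment blocks). Includes a synthetic-genome
    generator with planted ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
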