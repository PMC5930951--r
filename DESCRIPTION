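Package: consnp
Title: Conserved-Allele Regulatory SNP Discovery and Reporter Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering candidate regulatory SNPs (rSNPs) from
    strict cross-species conservation. Calls genomic segments that are exactly
    identical across a set of aligned species (human/mouse/chicken style MAF
    alignments) and at least a minimum length, intersects them with
    frequency-validated SNPs, masks exonic regions, scans for SOX10 monomeric
    and head-to-head dimeric consensus sites, prioritizes candidates by
    ChIP-Seq peak overlap, builds major/minor/deletion allele sequence
    variants, and scores dual-luciferase reporter assays with renilla
    normalization, a strict five-fold activity rule, and major-versus-minor
    allele contrasts. Includes a seeded synthetic-fixture generator (three
    diverged genomes with planted identical islands, SNPs, exons, motifs,
    peaks, and reporter plates) so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
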