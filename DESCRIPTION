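Package: allosweep
Title: K-mer Size and Coverage-Cutoff Sweeps for Allopolyploid
    Transcriptome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates allopolyploid transcriptomes (homeologous gene
    copies at controlled identity, skewed expression, short reads with a
    position-dependent error profile) and studies how de Bruijn graph
    k-mer size and k-mer coverage cutoff jointly determine transcript
    assembly success. Includes quality trimming, a minimal canonical
    k-mer assembler with a (k, cutoff) grid sweep, contig-to-reference
    alignment and complete-transcript calling, bounded-mismatch read
    mapping with RPKM quantification, greedy overlap merging with
    homeologue/orthologue/paralogue classification, a truth-based
    chimera audit, and assembly comparison metrics (N50/N90, overlap
    statistic, per-gene parameter profiles, expression correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    withr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
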