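Package: hrescan
Title: Hypoxia-Responsive Element Discovery in Promoter Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans promoter sequences for hypoxia-responsive elements (HREs),
    the [A/G]CGTG core motifs bound by HIF transcription factors, scores each
    candidate over a 33-bp window (8 bp upstream to 20 bp downstream of the
    core) with a position-specific frequency matrix, and classifies confident
    sites by a normalized probability threshold. Confident windows from two
    species are paired by exact global alignment to call conserved HREs.
    Includes degenerate (IUPAC) scanning for auxiliary hypoxia motifs,
    transcription-factor co-factor overlap, and a synthetic promoter
    generator with planted, matrix-drawn HRE windows and recorded ground
    truth so every pipeline stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
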