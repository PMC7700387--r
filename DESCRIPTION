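Package: utr5scan
Title: Annotation of 5'UTR Translational Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans spliced 5'UTR sequences for upstream ATG codons and
    upstream open reading frames, grades start-codon flanking (Kozak)
    context on a four-level scale, detects candidate RNA
    G-quadruplex-forming regions with three complementary detectors and an
    intersection consensus, counts stem loops in dot-bracket secondary
    structures (with a maximum-pairing fallback folder), profiles ortholog
    multiple sequence alignments for conserved subregions and vertebrate
    uATG conservation categories, builds neighbor-joining trees, annotates
    sequence variants against the resulting feature map, converts ribosome
    profiling coverage into qualitative occupancy scores, and assembles
    per-gene feature tables with descriptive and nonparametric correlation
    statistics. Includes curated reference annotations for the human ABCA
    transporter subfamily and seeded simulators producing every input with
    ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
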