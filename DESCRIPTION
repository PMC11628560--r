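Package: mefi
Title: Fragmentomics of Circulating Cell-Free Mitochondrial DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for mitochondrial evaluation of fragmentomics for
    cancer investigation (MEFI) from circulating cell-free mitochondrial
    DNA (ccf-mtDNA). Extracts per-site fragmentation profiles (long/short
    coverage-depth ratios with LOESS GC correction and z-scaling), 5' end
    base preferences and 4-mer end-motif diversity scores, and peak and
    window features on the circular mitochondrial genome; calls filtered
    heteroplasmic variants and relative mtDNA copy number; trains and
    evaluates random-forest cancer-detection and tissue-of-origin
    classifiers; and simulates fragment cohorts with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    randomForest,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
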