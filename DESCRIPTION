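Package: ribocall
Title: Identification of Actively Translated Open Reading Frames from
    Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls actively translated open reading frames (ORFs) from
    aligned ribosome-profiling data. Calibrates read-length dependent
    5'-end to A-site offsets against canonical coding regions, computes
    3-nt periodicity (codon-position read fractions) and read-uniformity
    (percentage of maximum entropy, PME) features per candidate ORF, and
    classifies ORFs with a radial-basis support vector machine trained on
    canonical ORFs versus off-frame and short non-coding RNA ORFs.
    Includes transcript annotation handling (genePred/GTF), near-cognate
    start ORF enumeration with representative-start selection, expression
    calling (Poisson test with Benjamini-Hochberg correction), translation
    efficiency and cytosol:nucleus ratios, Nei-Gojobori Ka/Ks estimation
    for homologous peptide pairs, and a synthetic ribosome-profiling
    simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    e1071,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
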