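Package: aarscan
Title: Tandem Amino Acid Repeat Analysis for Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and comparative analysis of tandem amino acid repeats
    (homopeptides) in protein-coding genes. Computes repeat content (RRPK,
    repeated residues per kilo amino acids) and its coupling to coding-sequence
    GC content, classifies repeat conservation within ortholog multiple
    alignments, estimates dN/dS in repeat flanking regions with a
    Nei-Gojobori (1986) codon-counting estimator, tests enrichment of
    structural disorder in repeats with a random-segment permutation null,
    and compares transcript-level regulation (tissue specificity, mRNA
    half-life, splice-class repeat content, recombination-hotspot proximity)
    between repeat-containing and repeat-free proteins. A seeded synthetic
    proteome generator produces orthologous sequence bundles with known
    ground truth so every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
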