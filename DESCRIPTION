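Package: stopshift
Title: Comparative Genomics Under a Genetic Code with All Three Stop Codons Reassigned
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trypanosomatid genomes in which UGA is read as
    tryptophan, UAG as glutamate, and UAA carries a dual meaning (glutamate
    in-frame, sole translation terminator at the coding-sequence end).
    Implements homology-guided gene-model construction under the reassigned
    code (HSP merging, boundary extension to in-frame AUG/UAA, spliced-leader
    start correction, overlap reduction), genuine-stop identification,
    in-frame reassigned-codon usage statistics and codon adaptation indices,
    background-normalised stop-context enrichment with a resampled Bonferroni
    binomial test and Cohen's-h sample sizing, read-depth somy classification
    by median-of-means ratios, GC and conserved-site analyses across species,
    and a synthetic-genome generator that plants every property the pipeline
    estimates so the whole analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
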