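Package: grazetx
Title: Differential Expression and Candidate-Gene Discovery in Unreplicated
    Three-Library Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for comparing unreplicated RNA-seq
    libraries from a grazing-tolerance study design: an exact conditional
    Poisson test for differential expression between two libraries without
    replicates, FPKM normalisation, Benjamini-Hochberg q-values,
    hypergeometric over-representation of GO terms and KEGG pathways with a
    dual-context (grazing response x differential tolerance) selection rule,
    classification of candidate genes by their expression pattern across
    three transcriptomes, SNP filtering with IUPAC ambiguity codes and
    synonymous/nonsynonymous annotation, Welch two-sample t-tests from
    summary statistics, and a synthetic three-library experiment generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
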