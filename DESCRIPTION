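Package: uvspectra
Title: UV Photoproduct Mutation Spectra, Strand Asymmetry and Lesion
    Quantification in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide UV mutation spectra in
    photolyase-expressing yeast mutation-accumulation experiments. Reads
    per-isolate variant calls, applies depth/allele-fraction/recurrence
    filtering, builds trinucleotide SBS-96 and doublet (DBS) mutation
    spectra, attributes mutation classes to cyclobutane pyrimidine dimers
    (CPDs), 6-4 photoproducts and atypical photoproducts by photolyase
    subtraction with Welch's t-tests, computes trinucleotide-normalized
    transcriptional strand-asymmetry statistics with chi-squared tests and
    Bonferroni correction, estimates lesion frequencies from alkaline-gel
    densitometry via Poisson fragment statistics, and combines the two to
    estimate the mutagenic potential of each photoproduct class. Includes
    a synthetic-cohort simulator with channel-specific photoproduct
    spectra, configurable photolyase repair and transcription-coupled
    repair bias, providing ground truth for every downstream statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
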