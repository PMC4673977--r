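Package: bsvar
Title: SNP Calling and Genotype-Corrected Methylation from Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls single-nucleotide variants from bisulfite-sequencing
    alignments (WGBS/RRBS) using a strand-separated per-chromosome pileup
    ("dynamic matrix"), frequency-based candidate filtering and an approximate
    Bayesian diploid genotyper that treats Watson-strand C/T and Crick-strand
    G/A observations as bisulfite-ambiguous, then reports genotype-corrected
    methylation levels per CpG/CHG/CHH context. Includes a bisulfite read
    simulator with ground-truth genotypes and methylation levels, evaluation
    utilities, VCF and tab-delimited methylation output, broom-style tidiers
    and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
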