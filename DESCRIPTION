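Package: accelexon
Title: Assembly-Free Detection of Accelerated Coding-Exon Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects coding exons with an excess of high-quality nucleotide
    differences relative to their flanking introns from whole-genome shotgun
    read alignments, without requiring genome assemblies of the compared
    species. Reads from all orthologous and paralogous copies of a gene are
    summarized into a per-region composite sequence of binary difference
    flags; exonic and intronic per-nucleotide difference rates are compared
    with a one-sided binomial likelihood-ratio test calibrated against
    chi-squared with one degree of freedom; false discovery is controlled
    with Storey q-values; a cascade of coverage, intronic-rate, processed
    pseudogene, tandem-domain and tiling-path filters removes known artifact
    classes. Includes segmental-duplication enrichment statistics, a
    Nei-Gojobori (1986) dN/dS permutation test, and a deterministic
    two-species read simulator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
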