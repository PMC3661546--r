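Package: popgendiff
Title: Pairwise Population Genetic Differences for Genes and Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes population genetic differences between pairs of
    populations for gene regions and gene sets from bi-allelic SNP
    genotypes. Eleven per-gene features are supported, covering allele
    frequency (reference-oriented minor allele frequencies and the
    Weir-Cockerham FST estimator), linkage disequilibrium pattern
    (pairwise r2 and D', four-gamete-test haplotype blocks, block
    number, block size, SNP density and haplotype diversity from
    EM-estimated haplotype frequencies) and tagSNP transferability
    (tag percent, captured percent, average maximum r2). Gene-level
    differences are aggregated to equal-weight scores for gene sets
    such as KEGG pathways and GO categories, with symmetric difference
    matrices and reference-distribution summaries. A seeded synthetic
    data generator (Balding-Nichols differentiation with blockwise LD)
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    vcfR,
    fgsea,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
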