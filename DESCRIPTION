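Package: snpconcord
Title: Three-Platform SNP Genotype Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Concord", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes single-nucleotide variant calls from a whole-genome
    sequencing platform, an exome sequencing platform and a genotyping array
    onto a common autosomal target panel, classifies every (site, sample)
    triple by alternate-allele positivity, and summarises concordance per
    sample and across samples (pairwise and three-way concordant counts,
    Venn partitions, alternative-allele-count level matrices, commonly
    discordant sites). Annotates sites with read depth, GC content in a
    101-base window and homopolymer length, and models call discordance on
    those covariates by logistic regression within a +/- 1 SD depth window.
    Ships a deterministic simulator that generates a reference sequence,
    Hardy-Weinberg genotypes and per-platform error processes so the whole
    pipeline is testable from standard VCF/BED/FASTA/PED fixtures without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
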