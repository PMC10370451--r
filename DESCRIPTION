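Package: lceqtl
Title: eQTL Architecture from Low-Coverage Whole-Genome Genotype Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline linking low-coverage whole-genome
    genotype likelihoods to single-mRNA and module-level expression and to
    physiological traits. Provides genotype-likelihood numerics
    (allele-frequency EM, HWE posteriors, expected dosages, expected
    heterozygosity), two-locus haplotype EM r2 and LD decay, a
    score-test association engine with covariates, ANGSD-style site
    filters, Benjamini-Hochberg correction and distance pruning, module
    eigengene and module-membership summaries, and the downstream
    regulatory-architecture analyses: cis/trans classification with a
    chromosome-aware null, hotspot detection, regulatory-proximity
    annotation, heterozygosity comparison and module-sharing tests. A
    synthetic-data generator emulates the lcWGS + expression + trait
    structure of a wild-population study so that the full pipeline runs
    and is testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
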