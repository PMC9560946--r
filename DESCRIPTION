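Package: karyosnp
Title: Single-Nucleus SNP Filtering and Karyon Inference for
    Multinucleate Fungal Spores
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying intra-spore genetic diversity from
    single-nucleus sequencing of multinucleate fungal spores (arbuscular
    mycorrhizal fungi in particular). Implements per-nucleus haploid
    genotype calling from VCF read evidence, GATK-style site hard
    filtering on quality annotations, depth/allele-fraction cell masking,
    cross-nucleus missingness filtering, repeat-aware SNP density over a
    masked assembly, and a conservative homokaryon-versus-heterokaryon
    classifier based on nucleus clustering and a permutation null. A
    synthetic-spore simulator with MDA-style overdispersed coverage and
    locus dropout generates truth-tracked fixtures so every stage can be
    validated by parameter recovery without raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
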