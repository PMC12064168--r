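Package: trcompare
Title: Comparative Tandem Repeat Catalogs, Liftover, Homology and Population Genetics
Version: 0.1.0
Authors@R: person("TR", "Tools", email = "trtools@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of tandem repeats (TRs) between
    genome assemblies. Ingests Tandem Repeat Finder output, merges and filters
    TR catalogs, lifts intervals between assemblies natively from UCSC chain
    files, identifies putatively homologous TR pairs by bidirectional liftover
    with overlap and Needleman-Wunsch motif-similarity gating, and summarizes
    multi-sample TR genotype VCFs into per-locus population-genetic statistics
    (observed heterozygosity, Nei gene diversity, allele counts and length
    ranges). Includes a fully seeded synthetic-fixture generator producing
    paired toy genomes with planted homologous TRs, exact chain files, and
    cohort genotype VCFs, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    optparse,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
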