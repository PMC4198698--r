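Package: fedvarq
Title: Federated Variant Querying with Privacy-Tiered Aggregation
Version: 0.1.0
Authors@R:
    person("fedvarq", "developers", email = "fedvarq@example.org", role = c("aut", "cre"))
Description: Desk-scale framework for federated querying of sequence variants
    across multiple sequencing centers. Each center genotypes arbitrary genomic
    positions or regions directly from aligned reads using a built-in diploid
    genotype-likelihood caller (including reference-site genotyping), records
    are harmonized across genome builds via UCSC chain files, and results are
    aggregated under privacy tiers: full per-sample detail for samples in the
    user's active dataset, non-personal summary statistics (genotype counts,
    minor allele frequency, quality statistics) for everyone else, with
    pseudonymous identifiers as the only backlink to individual samples.
    Includes a synthetic-data module that generates complete federation
    fixtures (registries, cohorts with planted genotypes, pileups with
    controlled error, chain files) for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
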