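Package: ydiscover
Title: Y-Chromosome Subclade Discovery from Haploid Low-Coverage Genotype Calls
Version: 0.1.0
Authors@R: person("ydiscover", "developers", email = "ydiscover@example.org",
    role = c("aut", "cre"))
Description: Discovers phylogenetically informative Y-chromosome variants from
    haploid genotype calls. Samples are split into cases and controls by an
    anchor SNP; candidate variants pass a four-stage filter cascade
    (control-ancestral, non-singleton, no heterozygous-looking calls,
    pairwise phylogenetic compatibility); retained variants are collapsed
    into equivalent-marker blocks, assembled into a rooted perfect phylogeny,
    reconciled against a scaffold of named markers, and samples are placed at
    the tips. Includes a synthetic-data generator that emulates low-coverage
    (2-4x) haploid calling with per-read error, missingness and
    duplicated-region artefacts, so the whole pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
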