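Package: smearseq
Title: Noise-Aware Variant and Fusion Analysis for Bone Marrow Smear
    Targeted Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing myeloid neoplasms from archival bone
    marrow smear targeted sequencing data. Smear-derived DNA and RNA are
    degraded, so somatic variant calls from smears carry excess low
    allele-frequency noise relative to paired fresh bone marrow cells.
    The package classifies paired smear/cell call sets into shared and
    sample-unique variants, applies a multi-stage noise-reduction
    cascade (caller filter flags, hard filters, panel-of-normals
    subtraction, allele-frequency and population-frequency thresholds),
    estimates the smear noise boundary on the allele-frequency axis,
    summarises amplicon coverage uniformity with an exact rank-sum
    test, merges two fusion detectors into a consensus call checked
    against the ISCN karyotype, and parses coding HGVS spans for
    internal tandem duplications. A seeded synthetic-data generator
    with truth labels emulates smear degradation so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
biocViews: VariantDetection, Sequencing, QualityControl, SomaticMutation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'boundary.R'
    'concordance.R'
    'coverage.R'
    'filters.R'
    'fusion.R'
    'hgvs.R'
    'karyotype.R'
    'normalize.R'
    'pipeline.R'
    'simulate.R'
    'smearseq-package.R'
    'vcf-io.R'
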