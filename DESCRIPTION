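Package: genepyr
Title: Gene-Level Rare-Variant Pathogenicity Scoring and Biallelic
    Diagnosis Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-individual, per-gene GenePy pathogenicity scores
    from a multi-sample VCF by combining variant deleteriousness (CADD),
    population allele frequency and zygosity, aggregates them into a
    cohort score matrix, ranks individuals per gene with tie-retaining
    top-k outlier selection, and triages top-ranked undiagnosed
    individuals for putative missed biallelic (recessive) diagnoses using
    HPO phenotype overlap, trio-based variant phasing, ClinVar/ACMG
    classifications and a set of deprioritization flags. Includes a
    self-contained synthetic-cohort simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
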