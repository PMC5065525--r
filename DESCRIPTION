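Package: naivebench
Title: Molecular Benchmarks for Naive and Primed Human Pluripotency
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess naive versus primed human pluripotent stem cell
    states by their molecular signatures: locus-level transposable-element
    (TE) expression barcoding with differential-expression and family
    polarization summaries, concordance of stage-specific embryo features
    with the naive/primed axis, TE-gene expression coupling by distance,
    ChIP/input metaprofiles anchored at TE 5' ends, whole-genome bisulfite
    methylation summaries with an imprinted-DMR erasure classifier,
    X-chromosome status from promoter-CGI methylation and allele-specific
    expression, and a mitochondrial-qPCR chimera-contribution calculator.
    Includes seeded synthetic-data generators emulating the statistical
    structure of each input so the whole pipeline runs end-to-end at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    yaml,
    matrixStats,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
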