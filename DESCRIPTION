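Package: gliostage
Title: Oligodendrocyte-Lineage Staging and Molecular Subtyping of IDH-Mutant Gliomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping IDH-mutant (PM-type) gliomas onto the
    oligodendrocyte lineage from bulk transcriptomes, single-cell RNA-seq
    UMI counts, and DNA methylation beta values. Implements differential
    expression against non-tumor brain with stage-signature enrichment
    percentages, a two-tier transcriptome classifier (EM/PM subtype, then
    1p19q co-deletion status via a packaged 152-gene classifier),
    marker-panel single-cell staging with malignancy and proliferation
    calls, expression-based inference of arm-level copy-number changes,
    and differentially methylated position analysis of myelination versus
    OPC-regulator promoters. Ships deterministic synthetic-data generators
    that emulate the assumed statistical structure of each data type, so
    the full pipeline is testable without controlled-access downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    zoo
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
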