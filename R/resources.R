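#' Packaged 152-gene 1p19q classifier
#'
#' Returns the transcriptome classifier used to split PM (IDH-mutant) gliomas
#' into 1p19q co-deleted versus non-co-deleted groups: 152 gene symbols,
#' derived from REMBRANDT PM gliomas with SNP-confirmed 1p19q status. Symbols
#' are upper-cased and returned in their published order. Several entries are
#' legacy identifiers (e.g. C1ORF144, LOC257396); downstream matching simply
#' drops symbols absent from a dataset and reports the count.
#'
#' @return A [signature_collection()] with the single set `classifier_1p19q`.
#' @export
load_packaged_1p19q_classifier <- function() {
  path <- system.file("extdata", "classifier_1p19q.txt", package = "gliostage")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged 1p19q classifier resource is missing; broken installation")
  genes <- toupper(readLines(path))
  signature_collection(
    list(classifier_1p19q = genes),
    provenance = c(classifier_1p19q =
      "152-gene transcriptome classifier of 1p19q co-deletion status in PM gliomas"))
}

load_packaged_gmt <- function(fname) {
  path <- system.file("extdata", fname, package = "gliostage")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged resource is missing: ", fname)
  read_signature_collection(path)
}

#' Packaged single-cell marker panels
#'
#' Canonical marker panels for cell-population assignment: pre-OPC, OPC, COP,
#' astrocyte, APC, oligodendrocyte, T cell, microglia, macrophage, and a
#' proliferation panel (MKI67, TOP2A, CCNB2, CDK1) used for the concomitant
#' proliferating-cell call.
#'
#' @return A [signature_collection()].
#' @export
load_marker_panels <- function() load_packaged_gmt("marker_panels.gmt")

#' Packaged oligodendrocyte-lineage stage signatures (synthetic defaults)
#'
#' Stage signatures for OPC, COP, NFOL, MFOL and MO. Each set couples a few
#' canonical anchor genes to simulated filler symbols (prefix `SYN`), giving
#' set sizes large enough for non-trivial enrichment percentages. These are
#' synthetic testing defaults: for real analyses supply stage signatures
#' derived from purified lineage populations via
#' [read_signature_collection()].
#'
#' @return A [signature_collection()].
#' @export
load_stage_signatures <- function() load_packaged_gmt("stage_signatures_synthetic.gmt")

#' Packaged EM/PM module signatures (synthetic defaults)
#'
#' EM (EGFR-module) and PM (PDGFRA-module) signature sets built from the
#' canonical module regulators plus simulated filler symbols. Synthetic
#' testing defaults; supply the published module gene lists for real cohorts.
#'
#' @return A [signature_collection()].
#' @export
load_em_pm_signatures <- function() load_packaged_gmt("em_pm_signatures_synthetic.gmt")

#' Packaged myelination / OPC-regulator gene sets
#'
#' The myelination set contains the MO marker GALC, myelin components (MAG,
#' MBP, MOBP, MOG) and the myelination regulators MYRF and SOX10; the
#' opc_regulators set contains regulators of OPC specification and
#' maintenance (MYT1, OLIG2, PDGFRA, PTPRZ1, SMOC1, SOX8). Used by the
#' methylation module for promoter-status summaries.
#'
#' @return A [signature_collection()].
#' @export
load_methylation_gene_sets <- function() load_packaged_gmt("methylation_gene_sets.gmt")
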