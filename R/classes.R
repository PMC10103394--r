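#' Expression matrix container
#'
#' Light container for a genes x samples (bulk, log2 scale) or genes x cells
#' (UMI raw counts) expression matrix. Values may be a base matrix or a
#' [Matrix::sparseMatrix()]; row names are gene symbols, column names sample
#' or cell identifiers.
#'
#' @param values numeric matrix or sparse Matrix with rownames (gene symbols)
#'   and colnames (sample/cell ids).
#' @param scale `"log2"` for log2-transformed expression, `"raw_counts"` for
#'   UMI counts (must be non-negative integers).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale = c("log2", "raw_counts")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need rownames (genes) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids; collapse duplicates before construction")
  if (scale == "raw_counts") {
    v <- if (inherits(values, "sparseMatrix")) values@x else values
    if (any(v < 0) || any(v != round(v)))
      stop("raw_counts must be non-negative integers")
  }
  structure(
    list(values = values,
         gene_ids = rownames(values),
         sample_ids = colnames(values),
         scale = scale),
    class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Gene annotation table
#'
#' Validates a per-gene annotation `data.frame` with chromosome, arm and
#' coordinate columns. Coordinates are 0-based half-open; `tss` is the
#' transcription start position used for promoter CpG mapping.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `arm` ("p"/"q"),
#'   `start`, `end`, `tss`.
#' @return The validated data.frame with class `GeneAnnotation` prepended.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "arm", "start", "end", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$start >= df$end)) stop("annotation requires start < end")
  if (!all(df$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  df$gene_id <- toupper(df$gene_id)
  class(df) <- c("GeneAnnotation", class(df))
  df
}

#' Named gene-set collection
#'
#' @param sets named list of character vectors of gene symbols. Symbols are
#'   upper-cased and de-duplicated within each set.
#' @param provenance optional named character vector of free-text provenance,
#'   one entry per set.
#' @return An object of class `SignatureCollection`.
#' @export
signature_collection <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) stop("empty gene set(s): ", paste(empty, collapse = ", "))
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    provenance <- stats::setNames(as.character(provenance[names(sets)]), names(sets))
    provenance[is.na(provenance)] <- ""
  }
  structure(list(sets = sets, provenance = provenance),
            class = "SignatureCollection")
}

#' @export
print.SignatureCollection <- function(x, ...) {
  cat(sprintf("SignatureCollection with %d set(s):\n", length(x$sets)))
  for (nm in names(x$sets))
    cat(sprintf("  %s (%d genes)\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Methylation beta-value matrix
#'
#' @param values CpG x samples matrix of beta values in \[0, 1\] with CpG ids
#'   as rownames and sample ids as colnames.
#' @param coords data.frame with columns `cpg_id`, `chrom`, `pos` covering
#'   every row of `values`.
#' @return An object of class `BetaMatrix`.
#' @export
beta_matrix <- function(values, coords) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta values need rownames (CpGs) and colnames (samples)")
  if (anyDuplicated(rownames(values))) stop("duplicate CpG ids")
  if (any(values < 0 | values > 1)) stop("beta values must lie in [0, 1]")
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(coords)))
    stop("coords needs columns: ", paste(need, collapse = ", "))
  miss <- setdiff(rownames(values), coords$cpg_id)
  if (length(miss))
    stop(length(miss), " CpG(s) missing from the coordinate manifest")
  coords <- coords[match(rownames(values), coords$cpg_id), , drop = FALSE]
  rownames(coords) <- NULL
  structure(list(values = values,
                 cpg_ids = rownames(values),
                 cpg_coords = coords,
                 sample_ids = colnames(values)),
            class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Default analysis thresholds
#'
#' Central bundle of the pipeline's tunable cutoffs. Defaults follow the
#' published workflow: top-N differential genes (2000 for array cohorts, 1000
#' for RNA-seq cohorts), fold-change 1.5, classifier derivation at p = 1e-16,
#' single-cell QC at 200 transcripts/cell and 3 cells/gene, 500 variable
#' features, DMPs at BH q < 0.05 with |delta beta| > 0.20, and MDS over the
#' top 1000 most variable CpGs.
#'
#' @param ... named overrides of any default element.
#' @return A named list of class `gliostage_thresholds`.
#' @export
default_thresholds <- function(...) {
  th <- list(
    de_top_n = 2000,
    fc_min = 1.5,
    de_p = 0.05,
    de_q = 0.05,
    classifier_p = 1e-16,
    min_transcripts_per_cell = 200,
    min_cells_per_gene = 3,
    n_features = 500,
    pc_p_cut = 1e-10,
    cnv_clip = c(strt_seq = 1.0, smart_seq2 = 1.0, tenx = 0.1),
    dmp_q = 0.05,
    dmp_delta_beta = 0.20,
    mds_top_cpgs = 1000)
  over <- list(...)
  bad <- setdiff(names(over), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(over)] <- over
  if (any(unlist(th[c("de_top_n", "fc_min", "min_transcripts_per_cell",
                      "min_cells_per_gene", "n_features", "mds_top_cpgs")]) <= 0))
    stop("thresholds must be positive")
  stopifnot(th$de_p > 0, th$de_p <= 1, th$de_q > 0, th$de_q <= 1,
            th$dmp_q > 0, th$dmp_q <= 1)
  class(th) <- "gliostage_thresholds"
  th
}
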