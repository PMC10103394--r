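#' Read an expression matrix
#'
#' Reads either a dense tab-separated matrix (first column `gene`, one column
#' per sample; assumed log2 scale) or a MatrixMarket triplet directory with
#' companion `features.tsv` / `barcodes.tsv` files (assumed raw UMI counts).
#' Gene symbols are upper-cased; duplicated symbols are collapsed by the
#' element-wise per-gene maximum (multiple array probe sets per gene), with a
#' warning reporting how many rows were merged.
#'
#' @param path file path (dense TSV) or directory (MTX triplet with
#'   `matrix.mtx`, `features.tsv`, `barcodes.tsv`).
#' @param layout `"tsv_dense"` or `"mtx_triplet"`.
#' @return An [expression_matrix()] (`scale` `"log2"` for dense,
#'   `"raw_counts"` for triplet input).
#' @export
read_expression_matrix <- function(path, layout = c("tsv_dense", "mtx_triplet")) {
  layout <- match.arg(layout)
  if (layout == "tsv_dense") {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "gene")
      stop("parse error at line 1 of ", path, ": first column must be 'gene'")
    if (ncol(df) < 2) stop("parse error: no sample columns in ", path)
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("parse error: non-numeric expression values in ", path)
    rownames(vals) <- toupper(df$gene)
    vals <- collapse_duplicate_genes(vals)
    expression_matrix(vals, scale = "log2")
  } else {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stop("missing triplet component: ", f)
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    features <- toupper(readLines(feat))
    barcodes <- readLines(bc)
    if (nrow(m) != length(features))
      stop("structural error: ", nrow(m), " matrix rows but ",
           length(features), " features")
    if (ncol(m) != length(barcodes))
      stop("structural error: ", ncol(m), " matrix columns but ",
           length(barcodes), " barcodes")
    dimnames(m) <- list(features, barcodes)
    m <- collapse_duplicate_genes(m)
    expression_matrix(m, scale = "raw_counts")
  }
}

collapse_duplicate_genes <- function(vals) {
  dup <- duplicated(rownames(vals))
  if (!any(dup)) return(vals)
  n_merged <- sum(dup)
  genes <- unique(rownames(vals))
  dense <- if (inherits(vals, "Matrix")) as.matrix(vals) else vals
  out <- do.call(rbind, lapply(split(seq_len(nrow(dense)), rownames(dense))[genes],
    function(i) apply(dense[i, , drop = FALSE], 2, max)))
  rownames(out) <- genes
  warning(sprintf("collapsed %d duplicated gene row(s) by per-gene maximum",
                  n_merged), call. = FALSE)
  if (inherits(vals, "Matrix")) out <- Matrix::Matrix(out, sparse = TRUE)
  out
}

#' Write an expression matrix
#'
#' Inverse of [read_expression_matrix()]; round-trips byte-for-byte with it
#' for matrices written by this function.
#'
#' @param expr an [expression_matrix()].
#' @param path output file (dense TSV) or directory (MTX triplet).
#' @param layout `"tsv_dense"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path,
                                    layout = c("tsv_dense", "mtx_triplet")) {
  layout <- match.arg(layout)
  if (layout == "tsv_dense") {
    df <- data.frame(gene = expr$gene_ids, as_dense_values(expr),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- as(Matrix::Matrix(expr$values, sparse = TRUE), "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(expr$gene_ids, file.path(path, "features.tsv"))
    writeLines(expr$sample_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are
#' upper-cased and de-duplicated within each set; the description column is
#' kept as per-set provenance.
#'
#' @param path GMT file.
#' @return A [signature_collection()].
#' @export
read_signature_collection <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 tab-separated fields")
  nms <- vapply(fields, `[[`, "", 1)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  prov <- stats::setNames(vapply(fields, `[[`, "", 2), nms)
  signature_collection(sets, provenance = prov)
}

#' Write a GMT gene-set file
#'
#' @param sigs a [signature_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature_collection <- function(sigs, path) {
  lines <- vapply(names(sigs$sets), function(nm) {
    paste(c(nm, sigs$provenance[[nm]], sigs$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED-like gene annotation
#'
#' Tab-separated, no header, 0-based half-open coordinates, columns
#' `chrom, start, end, gene, arm, tss`.
#'
#' @param path annotation file.
#' @return A [gene_annotation()] data.frame.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene", "arm", "tss"))
  gene_annotation(data.frame(
    gene_id = df$gene, chrom = df$chrom, arm = df$arm,
    start = df$start, end = df$end, tss = df$tss,
    stringsAsFactors = FALSE))
}

#' Write a BED-like gene annotation
#'
#' @param annotation a [gene_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  df <- data.frame(annotation$chrom, annotation$start, annotation$end,
                   annotation$gene_id, annotation$arm, annotation$tss)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a methylation beta matrix with its CpG manifest
#'
#' @param path tab-separated beta matrix, first column `cpg`, one column per
#'   sample.
#' @param manifest BED-like CpG manifest: `chrom, pos, pos + 1, cpg_id`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, manifest) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "cpg")
    stop("parse error at line 1 of ", path, ": first column must be 'cpg'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$cpg
  man <- utils::read.delim(manifest, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "cpg_id"))
  beta_matrix(vals, data.frame(cpg_id = man$cpg_id, chrom = man$chrom,
                               pos = man$start, stringsAsFactors = FALSE))
}

#' Write a methylation beta matrix and its CpG manifest
#'
#' @param beta a [beta_matrix()].
#' @param path output TSV for the beta values.
#' @param manifest output BED-like manifest path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, manifest) {
  df <- data.frame(cpg = beta$cpg_ids, beta$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- data.frame(beta$cpg_coords$chrom, beta$cpg_coords$pos,
                    beta$cpg_coords$pos + 1, beta$cpg_coords$cpg_id)
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV with a required `sample_id` column.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata must contain a 'sample_id' column")
  df
}
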