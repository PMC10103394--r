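#' Call differentially methylated positions
#'
#' Per-CpG Welch t-test on beta values between tumor and normal groups over
#' their shared CpG universe, BH adjustment over all shared CpGs, and joint
#' filtering: BH q < `dmp_q` and |delta beta| strictly greater than
#' `dmp_delta_beta` (a difference of exactly 0.20 is excluded at the
#' default). Delta beta is tumor mean minus normal mean; status is `hyper`
#' for positive, `hypo` for negative delta.
#'
#' @param tumor,normal [beta_matrix()] objects with >= 2 samples each.
#' @param thresholds a [default_thresholds()] bundle (`dmp_q`,
#'   `dmp_delta_beta`).
#' @return `data.frame` of class `DMPSet` with columns `cpg_id`,
#'   `delta_beta`, `p_value`, `q_value`, `status`; the number of CpGs tested
#'   is attached as attribute `n_tested`.
#' @export
call_dmps <- function(tumor, normal, thresholds = default_thresholds()) {
  stopifnot(inherits(tumor, "BetaMatrix"), inherits(normal, "BetaMatrix"))
  shared <- intersect(tumor$cpg_ids, normal$cpg_ids)
  if (!length(shared)) stop("tumor and normal share no CpG")
  if (ncol(tumor$values) < 2 || ncol(normal$values) < 2)
    stop("each group needs at least 2 samples")
  x <- cbind(tumor$values[shared, , drop = FALSE],
             normal$values[shared, , drop = FALSE])
  nt <- ncol(tumor$values)
  res <- row_welch_t(x, seq_len(nt), nt + seq_len(ncol(normal$values)))
  q <- stats::p.adjust(res$p, method = "BH")
  keep <- q < thresholds$dmp_q & abs(res$diff) > thresholds$dmp_delta_beta
  out <- data.frame(
    cpg_id = shared[keep],
    delta_beta = res$diff[keep],
    p_value = res$p[keep],
    q_value = q[keep],
    status = ifelse(res$diff[keep] > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_tested") <- length(shared)
  class(out) <- c("DMPSet", class(out))
  out
}

#' Hypermethylated fraction of a DMP set
#'
#' Percentage of differentially methylated positions that are
#' hypermethylated in the tumor group; the statistic behind the
#' hypermethylator phenotype of IDH-mutant gliomas.
#'
#' @param dmps a `DMPSet` from [call_dmps()].
#' @return Percentage in \[0, 100\].
#' @export
hypermethylated_fraction <- function(dmps) {
  if (nrow(dmps) == 0)
    stop("empty DMP set; hypermethylated fraction undefined")
  100 * sum(dmps$status == "hyper") / nrow(dmps)
}

#' Promoter methylation status per gene
#'
#' Maps DMPs to genes whose TSS lies within `tss_window` bp of the CpG (same
#' chromosome), then summarizes each gene of the supplied gene sets: `hyper`
#' if more than half of its mapped DMPs are hypermethylated, `hypo`
#' symmetrically, `mixed` otherwise, `none` when no DMP maps to its promoter
#' window.
#'
#' @param dmps a `DMPSet`.
#' @param cpg_coords data.frame `cpg_id`, `chrom`, `pos` covering the DMPs
#'   (e.g. `beta$cpg_coords`).
#' @param annotation a [gene_annotation()] (uses `tss`).
#' @param gene_sets a [signature_collection()], e.g.
#'   [load_methylation_gene_sets()].
#' @param tss_window promoter half-width in bp (default 1500).
#' @return `data.frame` with `gene`, `set`, `n_dmps`, `n_hyper`, `n_hypo`,
#'   `status`.
#' @export
summarize_promoter_status <- function(dmps, cpg_coords, annotation, gene_sets,
                                      tss_window = 1500) {
  if (tss_window <= 0) stop("tss_window must be positive")
  co <- cpg_coords[match(dmps$cpg_id, cpg_coords$cpg_id), , drop = FALSE]
  if (anyNA(co$pos)) stop("coordinates missing for some DMP CpGs")
  rows <- list()
  for (set_name in names(gene_sets$sets)) {
    for (g in gene_sets$sets[[set_name]]) {
      i <- match(g, annotation$gene_id)
      if (is.na(i)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, set = set_name, n_dmps = 0L, n_hyper = 0L, n_hypo = 0L,
          status = "none", stringsAsFactors = FALSE)
        next
      }
      hit <- strip_chr(co$chrom) == strip_chr(annotation$chrom[i]) &
        abs(co$pos - annotation$tss[i]) <= tss_window
      nh <- sum(dmps$status[hit] == "hyper")
      nl <- sum(dmps$status[hit] == "hypo")
      status <- if (nh + nl == 0) "none"
      else if (nh > (nh + nl) / 2) "hyper"
      else if (nl > (nh + nl) / 2) "hypo"
      else "mixed"
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, set = set_name, n_dmps = nh + nl, n_hyper = nh,
        n_hypo = nl, status = status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classical MDS of the most variable CpGs
#'
#' Ranks CpGs by across-sample variance, keeps the `top` most variable, and
#' embeds the samples in two dimensions by classical (Torgerson) scaling of
#' their Euclidean distances. The configuration is canonicalized by flipping
#' each axis so the first sample's coordinate is non-negative, making the
#' output deterministic.
#'
#' @param beta a [beta_matrix()] combining the groups to display.
#' @param top number of CpGs to keep (default 1000).
#' @return Samples x 2 coordinate matrix.
#' @export
mds_top_variable <- function(beta, top = 1000) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (top > nrow(beta$values)) stop("top exceeds the CpG count")
  if (ncol(beta$values) < 3) stop("need at least 3 samples")
  v <- apply(beta$values, 1, stats::var)
  keep <- names(sort(v, decreasing = TRUE))[seq_len(top)]
  sub <- beta$values[keep, , drop = FALSE]
  d <- stats::dist(t(sub))
  if (all(d == 0))
    stop("all samples identical on the selected CpGs; geometry degenerate")
  coords <- stats::cmdscale(d, k = 2)
  for (j in 1:2) if (coords[1, j] < 0) coords[, j] <- -coords[, j]
  colnames(coords) <- c("MDS1", "MDS2")
  coords
}
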