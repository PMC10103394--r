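#' Per-gene differential expression between two sample groups
#'
#' Welch (unequal-variance) two-sample t-test per gene on log2 expression,
#' with Benjamini-Hochberg adjustment over all tested genes. The log2 fold
#' change is the difference of group means (`group_a` minus `group_b`;
#' conventionally tumor minus non-tumor control). Genes with zero variance in
#' both groups are untestable and reported with t = 0, p = 1.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   length >= 2.
#' @return A `data.frame` of class `DEResult` with columns `gene`,
#'   `t_statistic`, `p_value`, `q_value`, `log2_fc`, `direction`.
#' @export
differential_expression <- function(expr, group_a, group_b) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "log2") stop("differential_expression expects log2 values")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  miss <- setdiff(c(group_a, group_b), expr$sample_ids)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  x <- as_dense_values(expr)
  res <- row_welch_t(x, match(group_a, expr$sample_ids),
                     match(group_b, expr$sample_ids))
  out <- data.frame(
    gene = expr$gene_ids,
    t_statistic = res$t,
    p_value = res$p,
    q_value = stats::p.adjust(res$p, method = "BH"),
    log2_fc = res$diff,
    direction = ifelse(res$diff >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DEResult", class(out))
  out
}

#' Select the top differentially expressed genes
#'
#' Ranks genes by ascending p-value (ties broken by descending |t|, then
#' lexicographic gene id), filters to the requested direction of change, then
#' truncates to the first `n`.
#'
#' @param de a `DEResult` from [differential_expression()].
#' @param n number of genes to keep (`<=` number of tested genes).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @return Character vector of gene ids, best-ranked first.
#' @export
select_top_genes <- function(de, n, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (n <= 0) stop("n must be positive")
  if (n > nrow(de)) stop("n exceeds the number of tested genes")
  keep <- if (direction == "both") rep(TRUE, nrow(de)) else de$direction == direction
  sub <- de[keep, , drop = FALSE]
  ord <- order(sub$p_value, -abs(sub$t_statistic), sub$gene)
  utils::head(sub$gene[ord], n)
}

#' Genes concordantly up-regulated in two comparisons
#'
#' Takes the top-`n` up-regulated gene lists of two differential-expression
#' results over the same gene universe (typically the 1p19q co-deleted and
#' non-co-deleted PM subtypes, each versus non-tumor brain), restricts each
#' list to genes with fold change >= `fc_min`, and intersects them.
#'
#' @param de_codel,de_noncodel `DEResult`s over an identical gene universe.
#' @param n top-list size per comparison.
#' @param thresholds a [default_thresholds()] bundle (uses `fc_min`).
#' @return A list with `genes` (the concordant set) and `venn`
#'   (`a_only`, `b_only`, `both`).
#' @export
concordant_up_genes <- function(de_codel, de_noncodel, n,
                                thresholds = default_thresholds()) {
  if (!setequal(de_codel$gene, de_noncodel$gene) ||
      nrow(de_codel) != nrow(de_noncodel))
    stop("the two DE results cover different gene universes")
  lfc_min <- log2(thresholds$fc_min)
  pass <- function(de) de$gene[de$log2_fc >= lfc_min]
  a <- intersect(select_top_genes(de_codel, n, "up"), pass(de_codel))
  b <- intersect(select_top_genes(de_noncodel, n, "up"), pass(de_noncodel))
  both <- intersect(a, b)
  list(genes = both,
       venn = c(a_only = length(setdiff(a, b)),
                b_only = length(setdiff(b, a)),
                both = length(both)))
}

#' Enrichment percentage of a signature gene set
#'
#' Fraction (as a percentage) of a stage-signature gene set that is enriched
#' in the tumor group of a differential-expression result, where "enriched"
#' means up-regulated with BH q < `de_q` and fold change >= `fc_min`. The
#' denominator is the number of signature genes present in the tested
#' universe.
#'
#' @param de a `DEResult`.
#' @param signature character vector of gene symbols (matched upper-case).
#' @param thresholds a [default_thresholds()] bundle (uses `de_q`, `fc_min`).
#' @param signature_name label used in error messages.
#' @return A list with `percentage`, `n_enriched`, `n_in_universe`.
#' @export
signature_enrichment_percentage <- function(de, signature,
                                            thresholds = default_thresholds(),
                                            signature_name = "signature") {
  signature <- unique(toupper(signature))
  present <- intersect(signature, de$gene)
  if (!length(present))
    stop("no gene of signature '", signature_name, "' is in the tested universe")
  sub <- de[de$gene %in% present, , drop = FALSE]
  hit <- sub$direction == "up" &
    sub$q_value < thresholds$de_q &
    sub$log2_fc >= log2(thresholds$fc_min)
  list(percentage = 100 * sum(hit) / length(present),
       n_enriched = sum(hit),
       n_in_universe = length(present))
}

#' Stage-signature enrichment profile
#'
#' Convenience wrapper applying [signature_enrichment_percentage()] to each
#' set of a signature collection, in the collection's order (for lineage
#' stage signatures: OPC, COP, NFOL, MFOL, MO).
#'
#' @param de a `DEResult`.
#' @param signatures a [signature_collection()].
#' @param thresholds a [default_thresholds()] bundle.
#' @return `data.frame` with columns `signature`, `percentage`, `n_enriched`,
#'   `n_in_universe`.
#' @export
stage_enrichment_profile <- function(de, signatures,
                                     thresholds = default_thresholds()) {
  rows <- lapply(names(signatures$sets), function(nm) {
    r <- signature_enrichment_percentage(de, signatures$sets[[nm]],
                                         thresholds, signature_name = nm)
    data.frame(signature = nm, percentage = r$percentage,
               n_enriched = r$n_enriched, n_in_universe = r$n_in_universe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
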