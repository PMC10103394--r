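#' Cluster samples by a signature gene set
#'
#' Restricts the expression matrix to the signature genes present, median
#' centers each gene across samples, and partitions the samples in
#' signature-correlation space. Two-group splits are initialized on the
#' leading principal component of the centered signature submatrix (1-D
#' k-means seeded at its quartiles); larger `k` is initialized by
#' agglomerative Ward clustering on 1 - Pearson correlation. Either
#' initialization is then refined to convergence by nearest-centroid
#' reassignment (each sample joins the cluster whose mean profile it
#' correlates with best). Every step is deterministic.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param signature character vector of gene symbols; at least 10 must be
#'   present in `expr`.
#' @param k number of clusters (default 2).
#' @return Named integer vector of cluster labels (1..k), one per sample.
#' @export
cluster_by_signature <- function(expr, signature, k = 2) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (ncol(expr$values) < 2 * k)
    stop("need at least ", 2 * k, " samples for k = ", k)
  signature <- unique(toupper(signature))
  found <- intersect(signature, expr$gene_ids)
  if (length(found) < 10)
    stop("only ", length(found), " of ", length(signature),
         " signature genes found in the matrix (need >= 10); missing: ",
         length(signature) - length(found))
  x <- as_dense_values(expr)[found, , drop = FALSE]
  x <- x - apply(x, 1, stats::median)
  if (k == 1)
    return(stats::setNames(rep(1L, ncol(x)), colnames(x)))
  if (k == 2) {
    pc1 <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)$x[, 1]
    centers <- stats::quantile(pc1, c(0.25, 0.75), names = FALSE)
    if (centers[1] == centers[2]) centers <- range(pc1)
    labels <- apply(abs(outer(pc1, centers, "-")), 1, which.min)
  } else {
    d <- stats::as.dist(1 - stats::cor(x))
    labels <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
  }
  labels <- refine_by_centroid(x, labels, k)
  stats::setNames(as.integer(labels), colnames(x))
}

# Converged nearest-centroid (Pearson) reassignment; keeps the previous
# labeling if a reassignment would empty a cluster or if any sample profile
# is constant (correlation undefined).
refine_by_centroid <- function(x, labels, k) {
  if (any(apply(x, 2, stats::sd) == 0)) return(labels)
  for (i in seq_len(50)) {
    centroids <- vapply(seq_len(k), function(g)
      rowMeans(x[, labels == g, drop = FALSE]), numeric(nrow(x)))
    if (any(apply(centroids, 2, stats::sd) == 0)) return(labels)
    new_labels <- apply(stats::cor(x, centroids), 1, which.max)
    if (length(unique(new_labels)) < k) return(labels)
    if (all(new_labels == labels)) break
    labels <- new_labels
  }
  labels
}

#' Orient two PM clusters as 1p19q co-deleted vs non-co-deleted
#'
#' Arm-level hemizygous loss reduces the expression dosage of genes on 1p and
#' 19q, so among two clusters of PM samples the cluster with the lower mean
#' expression of classifier genes located on 1p/19q is labeled `codel`.
#' The confidence is the absolute difference of the two cluster means
#' (log2 units).
#'
#' @param expr log2-scale [expression_matrix()].
#' @param labels two-valued cluster labels named by sample id (from
#'   [cluster_by_signature()]).
#' @param classifier character vector of classifier gene symbols.
#' @param annotation a [gene_annotation()]; at least 5 classifier genes must
#'   map to arm 1p or 19q.
#' @return `data.frame` with columns `sample_id`, `tier2` (`"codel"` /
#'   `"noncodel"`), `confidence`.
#' @export
orient_1p19q_clusters <- function(expr, labels, classifier, annotation) {
  if (length(unique(labels)) != 2)
    stop("orientation requires exactly 2 clusters")
  classifier <- unique(toupper(classifier))
  onarm <- annotation$gene_id[arm_label(annotation$chrom, annotation$arm)
                              %in% c("1p", "19q")]
  dosage_genes <- intersect(intersect(classifier, onarm), expr$gene_ids)
  if (length(dosage_genes) < 5)
    stop("only ", length(dosage_genes), " classifier genes map to 1p/19q ",
         "under this annotation (need >= 5); supply reference centroids instead")
  x <- as_dense_values(expr)[dosage_genes, names(labels), drop = FALSE]
  cl <- sort(unique(labels))
  means <- vapply(cl, function(g) mean(x[, labels == g, drop = FALSE]), 0)
  margin <- abs(diff(means))
  if (margin == 0)
    stop("orientation score is 0 (identical cluster means on 1p/19q); ",
         "refusing to guess - supply reference centroids")
  codel_cluster <- cl[which.min(means)]
  data.frame(
    sample_id = names(labels),
    tier2 = ifelse(labels == codel_cluster, "codel", "noncodel"),
    confidence = margin,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-tier ontogeny classification of a glioma cohort
#'
#' Tier 1 splits samples into EM versus PM by signature clustering on the
#' union of the EM and PM module signatures; each cluster is then oriented by
#' its per-sample module score (mean PM-signature minus mean EM-signature
#' expression): clusters whose mean score is positive are PM. Tier 2 clusters
#' the PM samples with the 1p19q classifier and orients the two clusters by
#' 1p/19q gene dosage ([orient_1p19q_clusters()]). Cohorts whose PM subset
#' has fewer than 4 samples skip tier 2 with a warning.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param em_signature,pm_signature disjoint character vectors of module
#'   genes.
#' @param classifier character vector; defaults to the packaged 152-gene
#'   1p19q classifier.
#' @param annotation a [gene_annotation()].
#' @return `data.frame` with columns `sample_id`, `tier1` (`"EM"`/`"PM"`),
#'   `tier2` (`"codel"`/`"noncodel"`/`"not_applicable"`), `confidence`.
#' @export
two_tier_classify <- function(expr, em_signature, pm_signature,
                              classifier = load_packaged_1p19q_classifier()$sets$classifier_1p19q,
                              annotation) {
  em_signature <- unique(toupper(em_signature))
  pm_signature <- unique(toupper(pm_signature))
  if (length(intersect(em_signature, pm_signature)))
    stop("EM and PM signatures must be disjoint")
  labels <- cluster_by_signature(expr, union(em_signature, pm_signature), k = 2)
  x <- as_dense_values(expr)
  em_found <- intersect(em_signature, expr$gene_ids)
  pm_found <- intersect(pm_signature, expr$gene_ids)
  if (!length(em_found) || !length(pm_found))
    stop("EM and PM signatures must both be present in the matrix")
  score <- colMeans(x[pm_found, , drop = FALSE]) -
    colMeans(x[em_found, , drop = FALSE])
  cluster_score <- tapply(score[names(labels)], labels, mean)
  tier1 <- ifelse(cluster_score[as.character(labels)] > 0, "PM", "EM")
  out <- data.frame(sample_id = names(labels), tier1 = tier1,
                    tier2 = "not_applicable", confidence = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  pm_samples <- out$sample_id[out$tier1 == "PM"]
  if (length(pm_samples) < 4) {
    if (length(pm_samples))
      warning("PM subset has fewer than 4 samples; tier 2 skipped")
    return(out)
  }
  pm_expr <- expression_matrix(expr$values[, pm_samples, drop = FALSE],
                               scale = "log2")
  pm_labels <- cluster_by_signature(pm_expr, classifier, k = 2)
  t2 <- orient_1p19q_clusters(pm_expr, pm_labels, classifier, annotation)
  idx <- match(t2$sample_id, out$sample_id)
  out$tier2[idx] <- t2$tier2
  out$confidence[idx] <- t2$confidence
  out
}

#' Derive a 1p19q-type classifier from a labeled cohort
#'
#' Utility reproducing how such a classifier is built from a training cohort
#' with known co-deletion status: per-gene Welch t-test between the two
#' groups, keeping genes (either direction) with p below a very stringent
#' cutoff (default 1e-16).
#'
#' @param expr log2-scale [expression_matrix()].
#' @param codel_samples,noncodel_samples sample id vectors.
#' @param p_cut p-value cutoff (default `classifier_p` = 1e-16).
#' @return Character vector of classifier gene symbols.
#' @export
derive_1p19q_classifier <- function(expr, codel_samples, noncodel_samples,
                                    p_cut = default_thresholds()$classifier_p) {
  de <- differential_expression(expr, codel_samples, noncodel_samples)
  de$gene[de$p_value < p_cut]
}
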