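#' Quality-control filter for a UMI count matrix
#'
#' Removes cells with fewer than `min_transcripts_per_cell` total transcripts
#' (strictly fewer: a cell with exactly 200 UMIs is retained at the default),
#' then genes detected in fewer than `min_cells_per_gene` of the remaining
#' cells. The order matters and is fixed: cells first, then genes.
#'
#' @param counts raw-count [expression_matrix()].
#' @param thresholds a [default_thresholds()] bundle.
#' @return List with `counts` (filtered [expression_matrix()]) and `report`
#'   (`removed_cells`, `removed_genes`, each with a reason attribute-free id
#'   vector).
#' @export
qc_filter <- function(counts, thresholds = default_thresholds()) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$scale != "raw_counts") stop("qc_filter expects raw UMI counts")
  v <- counts$values
  cell_tot <- Matrix::colSums(v)
  bad_cells <- colnames(v)[cell_tot < thresholds$min_transcripts_per_cell]
  v <- v[, !(colnames(v) %in% bad_cells), drop = FALSE]
  if (ncol(v) == 0)
    stop("all cells removed at the ", thresholds$min_transcripts_per_cell,
         "-transcript threshold")
  gene_cells <- Matrix::rowSums(v > 0)
  bad_genes <- rownames(v)[gene_cells < thresholds$min_cells_per_gene]
  v <- v[!(rownames(v) %in% bad_genes), , drop = FALSE]
  if (nrow(v) == 0) stop("all genes removed by the detected-cell threshold")
  list(counts = expression_matrix(v, scale = "raw_counts"),
       report = list(removed_cells = bad_cells, removed_genes = bad_genes))
}

#' Log-normalize a UMI count matrix
#'
#' Scales each cell to a fixed library size then applies `log2(1 + x)`.
#'
#' @param counts raw-count [expression_matrix()].
#' @param scale_factor target library size (default 1e4).
#' @return A log2-scale [expression_matrix()] (dense).
#' @export
lognormalize_counts <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$scale != "raw_counts") stop("expected raw UMI counts")
  v <- as_dense_values(counts)
  tot <- colSums(v)
  if (any(tot == 0)) stop("cells with zero total counts; run qc_filter first")
  norm <- log2(1 + sweep(v, 2, tot / scale_factor, "/"))
  expression_matrix(norm, scale = "log2")
}

#' Normalize, embed and cluster single cells
#'
#' Standard workflow: library-size normalization to a fixed scale with
#' `log2(1 + x)`, selection of the `n_features` most variable genes,
#' per-gene z-scaling (capped at |z| = 10), PCA, and graph-based (Louvain)
#' clustering on a k-nearest-neighbour graph in PC space. The number of
#' retained components is chosen by a deterministic variance rule: components
#' whose variance exceeds the mean component variance, capped at 20 and at
#' least 2.
#'
#' @param counts QC-filtered raw-count [expression_matrix()].
#' @param thresholds a [default_thresholds()] bundle (uses `n_features`).
#' @param seed integer seed controlling the (only) stochastic step, Louvain
#'   clustering.
#' @param knn neighbours for the cell graph (default 10).
#' @param scale_factor library-size target (default 1e4).
#' @return List with `normalized` (log2 [expression_matrix()]), `embedding`
#'   (cells x PCs), `clusters` (named integer vector), `n_pcs`.
#' @export
normalize_and_embed <- function(counts, thresholds = default_thresholds(),
                                seed = 1L, knn = 10, scale_factor = 1e4) {
  normalized <- lognormalize_counts(counts, scale_factor)
  x <- normalized$values
  n_feat <- thresholds$n_features
  if (nrow(x) < n_feat) {
    warning("fewer genes (", nrow(x), ") than n_features (", n_feat,
            "); using all genes")
    n_feat <- nrow(x)
  }
  vars <- apply(x, 1, stats::var)
  hvg <- names(sort(vars, decreasing = TRUE))[seq_len(n_feat)]
  xs <- x[hvg, , drop = FALSE]
  xs <- (xs - rowMeans(xs)) / pmax(apply(xs, 1, stats::sd), 1e-12)
  xs[xs > 10] <- 10; xs[xs < -10] <- -10
  pca <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)
  pvar <- pca$sdev^2
  n_pcs <- max(2, min(20, sum(pvar > mean(pvar)), length(pvar)))
  emb <- pca$x[, seq_len(n_pcs), drop = FALSE]
  clusters <- withr::with_seed(seed, knn_louvain(emb, knn))
  list(normalized = normalized, embedding = emb,
       clusters = clusters, n_pcs = n_pcs)
}

# Louvain community detection on a symmetrized kNN graph of the rows of emb.
knn_louvain <- function(emb, knn) {
  n <- nrow(emb)
  k <- min(knn, n - 1)
  d <- as.matrix(stats::dist(emb))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::cluster_louvain(g)
  stats::setNames(as.integer(igraph::membership(cl)), rownames(emb))
}

#' Annotate clusters with marker panels
#'
#' Per cluster and panel, the panel score is the mean (over the cluster's
#' cells) of each cell's mean normalized expression of the panel genes. Each
#' cluster is typed by its best-scoring panel (the proliferation panel is
#' excluded from typing). Clusters whose best score falls below a positivity
#' floor are left `unassigned`; the floor is the 90th percentile of the
#' corresponding panel's scores under cluster-label permutation nulls.
#' Independently of cluster typing, a cell is flagged `proliferating` when
#' every gene of the proliferation panel is detected (> 0) in that cell.
#'
#' @param normalized log2-normalized [expression_matrix()].
#' @param clusters named integer vector of cluster labels per cell.
#' @param panels a [signature_collection()] of marker panels (default the
#'   packaged panels).
#' @param prolif_panel name of the proliferation panel within `panels`.
#' @param n_perm permutations for the positivity floor (default 50).
#' @param seed seed for the permutation nulls.
#' @return `data.frame` of class `CellAnnotation`: `cell_id`, `cluster`,
#'   `cell_type`, `proliferating`, `malignant` (initialized `NA`), plus one
#'   `score_<panel>` column per panel. Cluster-level panel scores are
#'   attached as attribute `cluster_scores`.
#' @export
annotate_clusters <- function(normalized, clusters,
                              panels = load_marker_panels(),
                              prolif_panel = "proliferation",
                              n_perm = 50, seed = 1L) {
  stopifnot(inherits(normalized, "ExpressionMatrix"))
  x <- as_dense_values(normalized)[, names(clusters), drop = FALSE]
  panel_genes <- lapply(panels$sets, intersect, y = rownames(x))
  empty <- names(panel_genes)[lengths(panel_genes) == 0]
  if (length(empty))
    stop("no genes of panel(s) found in the matrix: ",
         paste(empty, collapse = ", "))
  # cells x panels matrix of per-cell mean panel expression
  cell_scores <- vapply(panel_genes, function(g)
    colMeans(x[g, , drop = FALSE]), numeric(ncol(x)))
  cl_ids <- sort(unique(clusters))
  cluster_scores <- t(vapply(cl_ids, function(cl)
    colMeans(cell_scores[clusters == cl, , drop = FALSE]),
    numeric(ncol(cell_scores))))
  rownames(cluster_scores) <- cl_ids
  typing_panels <- setdiff(colnames(cluster_scores), prolif_panel)
  floors <- withr::with_seed(seed, {
    perm <- replicate(n_perm, {
      pl <- sample(clusters)
      t(vapply(cl_ids, function(cl)
        colMeans(cell_scores[pl == cl, , drop = FALSE]),
        numeric(ncol(cell_scores))))
    })
    apply(matrix(aperm(perm, c(1, 3, 2)), ncol = ncol(cell_scores),
                 dimnames = list(NULL, colnames(cell_scores))),
          2, stats::quantile, probs = 0.9)
  })
  best <- typing_panels[apply(cluster_scores[, typing_panels, drop = FALSE],
                              1, which.max)]
  names(best) <- rownames(cluster_scores)
  type_of <- vapply(as.character(cl_ids), function(cl) {
    if (cluster_scores[cl, best[cl]] < floors[best[cl]]) "unassigned"
    else best[cl]
  }, "")
  pg <- panel_genes[[prolif_panel]]
  proliferating <- colSums(x[pg, , drop = FALSE] > 0) == length(pg)
  out <- data.frame(
    cell_id = names(clusters),
    cluster = as.integer(clusters),
    cell_type = type_of[as.character(clusters)],
    proliferating = unname(proliferating),
    malignant = NA,
    stringsAsFactors = FALSE, row.names = NULL)
  sc <- as.data.frame(cell_scores)
  names(sc) <- paste0("score_", names(panel_genes))
  out <- cbind(out, sc)
  attr(out, "cluster_scores") <- cluster_scores
  attr(out, "floors") <- floors
  class(out) <- c("CellAnnotation", class(out))
  out
}

#' Call malignant cells
#'
#' A cluster is called malignant when (i) its SOX2 positivity (fraction of
#' cells with detected SOX2) exceeds the highest positivity among the
#' non-malignant reference clusters (immune or oligodendrocyte typed) by more
#' than `margin`, and (ii) the majority of its cells carry at least one
#' arm-level CNV event. Immune- and oligodendrocyte-typed clusters are never
#' malignant. The call is cluster-level: sporadic single-cell SOX2 noise in a
#' reference population does not create malignant calls.
#'
#' @param annotations a `CellAnnotation` from [annotate_clusters()].
#' @param normalized log2-normalized [expression_matrix()] covering the same
#'   cells.
#' @param arm_calls per-cell arm event calls from [call_arm_events()].
#' @param sox2_gene symbol used for the stemness marker (default `"SOX2"`).
#' @param margin required positivity excess over the reference level.
#' @param cnv_majority fraction of cells of a cluster that must carry an
#'   event (default 0.5).
#' @return The annotations with the `malignant` column filled in.
#' @export
call_malignant <- function(annotations, normalized, arm_calls,
                           sox2_gene = "SOX2", margin = 0.05,
                           cnv_majority = 0.5) {
  never <- c("microglia", "macrophage", "T_cell", "oligodendrocyte")
  ref_clusters <- unique(annotations$cluster[annotations$cell_type %in% never])
  if (!length(ref_clusters))
    stop("no non-malignant reference cluster (immune/oligodendrocyte) found; ",
         "supply reference cell ids via the CNV step instead")
  x <- as_dense_values(normalized)
  if (!sox2_gene %in% rownames(x)) stop(sox2_gene, " not in the matrix")
  pos <- as.numeric(x[sox2_gene, annotations$cell_id] > 0)
  sox2_by_cluster <- tapply(pos, annotations$cluster, mean)
  ref_level <- max(sox2_by_cluster[as.character(ref_clusters)])
  ev <- arm_calls$summary
  has_event <- tapply(ev$n_events[match(annotations$cell_id, ev$cell_id)] > 0,
                      annotations$cluster, mean)
  cl <- as.character(annotations$cluster)
  annotations$malignant <-
    !(annotations$cell_type %in% never) &
    sox2_by_cluster[cl] > ref_level + margin &
    has_event[cl] >= cnv_majority
  annotations
}

#' Proliferating fraction of malignant cells per sample
#'
#' Percentage of malignant cells flagged proliferating, per sample, with the
#' cohort mean and SD over samples containing at least one malignant cell.
#' Samples without proliferating malignant cells are reported as 0% (the
#' "proliferation not detected" case); samples without malignant cells are
#' excluded from the cohort statistics and listed.
#'
#' @param annotations a `CellAnnotation` with malignancy calls.
#' @param sample_ids character vector assigning each cell (row of
#'   `annotations`) to a sample.
#' @return List with `per_sample` (`sample_id`, `n_malignant`,
#'   `n_proliferating`, `percent`), `cohort_mean`, `cohort_sd`,
#'   `excluded_samples`.
#' @export
proliferation_fraction <- function(annotations, sample_ids) {
  stopifnot(length(sample_ids) == nrow(annotations))
  if (all(is.na(annotations$malignant)))
    stop("malignancy calls missing; run call_malignant first")
  mal <- annotations$malignant %in% TRUE
  per <- do.call(rbind, lapply(unique(sample_ids), function(s) {
    i <- sample_ids == s
    nm <- sum(mal & i)
    np <- sum(mal & i & annotations$proliferating)
    data.frame(sample_id = s, n_malignant = nm, n_proliferating = np,
               percent = if (nm > 0) 100 * np / nm else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(per$percent)
  if (sum(ok) == 1)
    warning("single-sample cohort; SD reported as 0")
  list(per_sample = per,
       cohort_mean = mean(per$percent[ok]),
       cohort_sd = if (sum(ok) > 1) stats::sd(per$percent[ok]) else 0,
       excluded_samples = per$sample_id[!ok])
}

#' Correlate a cluster profile with lineage-stage references
#'
#' Pearson correlation between a mean expression profile (e.g. of a malignant
#' cluster) and per-stage reference profiles over the shared genes. Requires
#' at least 30 shared genes and non-constant vectors.
#'
#' @param cluster_profile named numeric vector (mean log-normalized
#'   expression).
#' @param reference_profiles genes x stages numeric matrix with rownames.
#' @return List with `r` (named per-stage correlations), `best_stage`,
#'   `n_shared_genes`.
#' @export
stage_correlation <- function(cluster_profile, reference_profiles) {
  shared <- intersect(names(cluster_profile), rownames(reference_profiles))
  if (length(shared) < 30)
    stop("only ", length(shared), " shared genes (need >= 30)")
  a <- cluster_profile[shared]
  if (stats::sd(a) == 0)
    stop("cluster profile is constant over the shared genes; ",
         "correlation undefined")
  r <- apply(reference_profiles[shared, , drop = FALSE], 2, function(b) {
    if (stats::sd(b) == 0)
      stop("a reference profile is constant over the shared genes; ",
           "correlation undefined")
    stats::cor(a, b)
  })
  list(r = r, best_stage = names(r)[which.max(r)],
       n_shared_genes = length(shared))
}
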