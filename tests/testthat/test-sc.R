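test_that("QC filter enforces the published boundaries exactly", {
  genes <- sprintf("G%02d", 1:6)
  cells <- sprintf("c%d", 1:4)
  m <- matrix(0L, 6, 4, dimnames = list(genes, cells))
  m[1, ] <- c(199L, 200L, 250L, 300L)   # cell totals via gene 1
  m[2, 2:4] <- 1L                        # detected in 3 cells -> kept
  m[3, 3:4] <- 1L                        # detected in 2 cells -> removed
  m[1, ] <- m[1, ] - colSums(m[2:6, , drop = FALSE])
  ex <- expression_matrix(m, "raw_counts")
  res <- qc_filter(ex)
  expect_identical(res$report$removed_cells, "c1")   # 199 < 200
  expect_true("c2" %in% colnames(res$counts$values)) # exactly 200 retained
  expect_true("G03" %in% res$report$removed_genes)
  expect_false("G02" %in% res$report$removed_genes)
  expect_error(qc_filter(ex, default_thresholds(min_transcripts_per_cell = 1e6)),
               "1e\\+06|1000000")
})

test_that("QC filter equals brute-force filtering on random fixtures", {
  set.seed(77)
  th <- default_thresholds(min_transcripts_per_cell = 20, min_cells_per_gene = 3)
  for (i in 1:100) {
    ng <- sample(5:20, 1); nc <- sample(5:20, 1)
    m <- matrix(rpois(ng * nc, 3), ng,
                dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%02d", 1:nc)))
    keep_cells <- colSums(m) >= 20
    if (!any(keep_cells)) next
    m2 <- m[, keep_cells, drop = FALSE]
    keep_genes <- rowSums(m2 > 0) >= 3
    if (!any(keep_genes)) next
    res <- qc_filter(expression_matrix(m, "raw_counts"), th)
    expect_identical(as.matrix(res$counts$values),
                     m2[keep_genes, , drop = FALSE])
  }
})

test_that("normalization fixes per-cell totals before the log", {
  set.seed(1)
  m <- matrix(rpois(300, 5) + 1L, 30,
              dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:10)))
  norm <- lognormalize_counts(expression_matrix(m, "raw_counts"))
  pre_log <- 2^as.matrix(norm$values) - 1
  expect_equal(unname(colSums(pre_log)), rep(1e4, 10), tolerance = 1e-8)
})

test_that("embedding separates and clustering recovers two populations", {
  s <- simulate_single_cell(small_sc_config(
    seed = 13, sc_cells = c(malignant = 120, microglia = 80)))
  q <- qc_filter(s$counts)
  emb <- normalize_and_embed(q$counts, seed = 2)
  truth <- s$cell_truth$cell_type[match(names(emb$clusters),
                                        s$cell_truth$cell_id)]
  # each truth population maps to its own set of clusters (ARI would be 1
  # after merging malignant subclusters): no cluster mixes the two types
  tab <- table(emb$clusters, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  # determinism given the seed
  emb2 <- normalize_and_embed(q$counts, seed = 2)
  expect_identical(emb$clusters, emb2$clusters)
})

test_that("marker-panel annotation types clusters and flags proliferation", {
  s <- simulate_single_cell(small_sc_config(seed = 17))
  q <- qc_filter(s$counts)
  emb <- normalize_and_embed(q$counts, seed = 3)
  ann <- annotate_clusters(emb$normalized, emb$clusters)
  truth <- s$cell_truth[match(ann$cell_id, s$cell_truth$cell_id), ]
  expect_true(all(ann$cell_type[truth$cell_type == "microglia"] == "microglia"))
  expect_true(all(ann$cell_type[truth$cell_type == "oligodendrocyte"] ==
                    "oligodendrocyte"))
  # malignant clusters carry the OPC/COP program
  expect_true(all(ann$cell_type[truth$cell_type == "malignant"] %in%
                    c("pre_OPC", "OPC", "COP")))
  # proliferating flag = concomitant detection of all four markers
  x <- as.matrix(emb$normalized$values)
  pg <- intersect(load_marker_panels()$sets$proliferation, rownames(x))
  expect_length(pg, 4)
  manual <- colSums(x[pg, ann$cell_id] > 0) == 4
  expect_equal(ann$proliferating, unname(manual))
})

test_that("a cell missing one proliferation marker is not proliferating", {
  genes <- c("MKI67", "TOP2A", "CCNB2", "CDK1", load_marker_panels()$sets$microglia,
             sprintf("F%02d", 1:20))
  set.seed(2)
  m <- matrix(rpois(length(genes) * 30, 2) + 1L, length(genes),
              dimnames = list(genes, sprintf("c%02d", 1:30)))
  m["TOP2A", ] <- 0L; m["TOP2A", 1:15] <- 5L
  m["MKI67", ] <- 5L; m["CCNB2", ] <- 5L; m["CDK1", ] <- 5L
  norm <- lognormalize_counts(expression_matrix(m, "raw_counts"))
  clusters <- setNames(rep(1:2, each = 15), colnames(m))
  pan <- load_marker_panels()
  panels <- signature_collection(pan$sets[c("proliferation", "microglia")])
  ann <- annotate_clusters(norm, clusters, panels, n_perm = 10)
  expect_true(all(ann$proliferating[1:15]))
  expect_false(any(ann$proliferating[16:30]))
})

test_that("all-zero clusters are left unassigned", {
  panels <- load_marker_panels()
  genes <- unique(c(unlist(panels$sets), sprintf("F%02d", 1:30)))
  set.seed(4)
  m <- matrix(rpois(length(genes) * 24, 2) + 1L, length(genes),
              dimnames = list(genes, sprintf("c%02d", 1:24)))
  mg <- panels$sets$microglia
  m[mg, 1:12] <- m[mg, 1:12] + 30L
  m[, 13:24] <- 0L
  m["F01", 13:24] <- 1L  # outside every panel; keeps library size non-zero
  norm <- lognormalize_counts(expression_matrix(m, "raw_counts"))
  clusters <- setNames(rep(1:2, each = 12), colnames(m))
  ann <- annotate_clusters(norm, clusters, panels, n_perm = 20)
  expect_true(all(ann$cell_type[1:12] == "microglia"))
  expect_true(all(ann$cell_type[13:24] == "unassigned"))
})

test_that("malignancy requires cluster-level SOX2 and a CNV event", {
  s <- simulate_single_cell(small_sc_config(seed = 19))
  q <- qc_filter(s$counts)
  emb <- normalize_and_embed(q$counts, seed = 5)
  ann <- annotate_clusters(emb$normalized, emb$clusters)
  refs <- ann$cell_id[ann$cell_type %in%
                        c("microglia", "oligodendrocyte", "T_cell")]
  cnv <- infer_cnv(emb$normalized, refs, s$annotation, window = 51)
  ev <- call_arm_events(cnv)
  ann2 <- call_malignant(ann, emb$normalized, ev)
  truth <- s$cell_truth$malignant <-
    s$cell_truth$cell_type[match(ann2$cell_id, s$cell_truth$cell_id)] ==
    "malignant"
  expect_gt(mean(ann2$malignant == truth), 0.95)
  expect_false(any(ann2$malignant[ann2$cell_type %in%
                                    c("microglia", "oligodendrocyte",
                                      "T_cell", "macrophage")]))
})

test_that("proliferation fractions aggregate correctly across samples", {
  ann <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    cluster = 1L, cell_type = "OPC",
    proliferating = c(rep(c(TRUE, FALSE, FALSE, FALSE), 5), rep(FALSE, 20)),
    malignant = c(rep(TRUE, 30), rep(FALSE, 10)),
    stringsAsFactors = FALSE)
  samples <- rep(c("sA", "sB"), each = 20)
  res <- proliferation_fraction(ann, samples)
  expect_equal(res$per_sample$percent[res$per_sample$sample_id == "sA"], 25)
  expect_equal(res$per_sample$percent[res$per_sample$sample_id == "sB"], 0)
  expect_equal(res$cohort_mean, 12.5)
  # single-sample cohort: SD degenerates to 0 with a warning
  expect_warning(one <- proliferation_fraction(ann[1:20, ], samples[1:20]),
                 "single-sample")
  expect_equal(one$cohort_sd, 0)
  # a sample with zero malignant cells is excluded and listed
  ann$malignant[21:40] <- FALSE
  expect_warning(res2 <- proliferation_fraction(ann, samples),
                 "single-sample")
  expect_identical(res2$excluded_samples, "sB")
})

test_that("stage correlation is exact on constructed profiles", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:60)
  ref <- matrix(rnorm(60 * 3, 5), 60, dimnames = list(genes, c("OPC", "COP", "MO")))
  r <- stage_correlation(setNames(ref[, "OPC"], genes), ref)
  expect_equal(unname(r$r["OPC"]), 1)
  expect_identical(r$best_stage, "OPC")
  anti <- stage_correlation(setNames(-ref[, "MO"] + 10, genes), ref)
  expect_equal(unname(anti$r["MO"]), -1)
  expect_error(stage_correlation(setNames(rep(1, 60), genes), ref),
               "constant")
  expect_error(stage_correlation(setNames(ref[1:10, 1], genes[1:10]), ref),
               ">= 30")
  # correlation decays monotonically with added noise (Monte-Carlo)
  sds <- c(0.1, 1, 4, 16)
  rs <- sapply(sds, function(s) {
    mean(replicate(20, stage_correlation(
      setNames(ref[, "OPC"] + rnorm(60, 0, s), genes), ref)$r["OPC"]))
  })
  expect_true(all(diff(rs) < 0))
})
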