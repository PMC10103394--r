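make_beta <- function(values, ids = NULL, samples = NULL) {
  if (is.null(ids)) ids <- sprintf("cg%04d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(ids, samples)
  beta_matrix(values, data.frame(cpg_id = ids, chrom = "1",
                                 pos = seq_len(nrow(values)) * 1000L))
}

test_that("identical groups give an empty DMP set; boundary is strict", {
  set.seed(3)
  v <- matrix(runif(200, 0.2, 0.8), 50)
  t1 <- make_beta(v[, 1:2]); n1 <- make_beta(v[, 1:2])
  expect_equal(nrow(call_dmps(t1, n1)), 0)
  # delta exactly 0.19 with a tiny p-value is still excluded (> 0.20 strict)
  base <- matrix(0.40, 20, 8) + matrix(rnorm(160, 0, 1e-4), 20)
  tum <- base; tum[1, ] <- tum[1, ] + 0.19; tum[2, ] <- tum[2, ] + 0.30
  dm <- call_dmps(make_beta(tum), make_beta(base))
  expect_false("cg0001" %in% dm$cpg_id)
  expect_true("cg0002" %in% dm$cpg_id)
  expect_identical(dm$status[dm$cpg_id == "cg0002"], "hyper")
  expect_true(all(abs(dm$delta_beta) > 0.20 & dm$q_value < 0.05))
})

test_that("DMP recall and FDR against spiked synthetic truth", {
  cfg <- sim_config(seed = 101, n_cpgs = 8000, n_genes = 600,
                    n_dmp_true = 500, beta_hyper_delta = 0.3)
  m <- simulate_methylomes(cfg)
  dm <- call_dmps(m$tumor, m$normal)
  truth <- c(m$truth$hyper, m$truth$hypo)
  recall <- length(intersect(dm$cpg_id, truth)) / length(truth)
  fdr <- if (nrow(dm)) length(setdiff(dm$cpg_id, truth)) / nrow(dm) else 0
  expect_gte(recall, 0.95)
  expect_lte(fdr, 0.05)
  # direction recovered
  expect_true(all(dm$status[dm$cpg_id %in% m$truth$hyper] == "hyper"))
  expect_true(all(dm$status[dm$cpg_id %in% m$truth$hypo] == "hypo"))
})

test_that("hypermethylated fraction is a simple ratio with guarded edges", {
  dm <- data.frame(cpg_id = c("a", "b", "c", "d"),
                   delta_beta = c(0.3, 0.3, 0.3, -0.3),
                   p_value = 1e-6, q_value = 1e-5,
                   status = c("hyper", "hyper", "hyper", "hypo"),
                   stringsAsFactors = FALSE)
  class(dm) <- c("DMPSet", class(dm))
  expect_equal(hypermethylated_fraction(dm), 75)
  expect_equal(hypermethylated_fraction(dm[dm$status == "hyper", ]), 100)
  expect_equal(hypermethylated_fraction(dm[3:4, ]), 50)
  expect_error(hypermethylated_fraction(dm[0, ]), "empty")
})

test_that("promoter status integrates DMP direction within the TSS window", {
  ann <- gene_annotation(data.frame(
    gene_id = c("MYEL1", "MIX1", "FAR1"), chrom = "1", arm = "p",
    start = c(10000L, 50000L, 90000L), end = c(11500L, 51500L, 91500L),
    tss = c(10000L, 50000L, 90000L)))
  coords <- data.frame(
    cpg_id = sprintf("cg%d", 1:6), chrom = "1",
    pos = c(9500L, 10200L, 10900L, 49600L, 50400L, 99000L))
  dm <- data.frame(
    cpg_id = sprintf("cg%d", 1:6),
    delta_beta = c(0.3, 0.3, 0.3, 0.3, -0.3, 0.3),
    p_value = 1e-8, q_value = 1e-6,
    status = c("hyper", "hyper", "hyper", "hyper", "hypo", "hyper"),
    stringsAsFactors = FALSE)
  class(dm) <- c("DMPSet", class(dm))
  sets <- signature_collection(list(myelination = c("MYEL1", "MIX1", "FAR1")))
  st <- summarize_promoter_status(dm, coords, ann, sets, tss_window = 1500)
  expect_identical(st$status[st$gene == "MYEL1"], "hyper")  # 3 hyper DMPs
  expect_identical(st$status[st$gene == "MIX1"], "mixed")   # 1 hyper + 1 hypo
  expect_identical(st$status[st$gene == "FAR1"], "none")    # cg6 is 9 kb away
})

test_that("synthetic promoter truth is recovered for >= 90% of set genes", {
  cfg <- sim_config(seed = 55, n_cpgs = 8000, n_genes = 600, n_dmp_true = 500)
  m <- simulate_methylomes(cfg)
  dm <- call_dmps(m$tumor, m$normal)
  u <- synthetic_gene_universe(cfg)
  gsets <- load_methylation_gene_sets()
  st <- summarize_promoter_status(dm, m$tumor$cpg_coords, u$annotation, gsets,
                                  tss_window = 1500)
  myel <- st[st$set == "myelination", ]
  opcr <- st[st$set == "opc_regulators", ]
  expect_gte(mean(myel$status == "hyper"), 0.9)
  expect_gte(mean(opcr$status == "hypo"), 0.9)
})

test_that("MDS is deterministic, distance-preserving, and separates groups", {
  # planar toy: 4 samples on a rectangle in CpG space, 2-embeddable
  v <- rbind(c(0, 3, 0, 3), c(0, 0, 4, 4))
  pad <- matrix(0.5, 8, 4)
  b <- make_beta((rbind(v / 10, pad)))
  xy <- mds_top_variable(b, top = 10)
  expect_equal(as.matrix(dist(xy)), as.matrix(dist(t(b$values[1:2, ]))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # identical samples land on identical coordinates
  v2 <- matrix(runif(40), 10); v2[, 2] <- v2[, 1]
  b2 <- make_beta(v2)
  xy2 <- mds_top_variable(b2, top = 10)
  expect_equal(xy2[1, ], xy2[2, ], tolerance = 1e-10)
  # tumor vs normal betas separate (silhouette > 0 proxy)
  cfg <- sim_config(seed = 77, n_cpgs = 5000, n_genes = 600, n_dmp_true = 400)
  m <- simulate_methylomes(cfg)
  comb <- beta_matrix(cbind(m$tumor$values, m$normal$values),
                      m$tumor$cpg_coords)
  xy3 <- mds_top_variable(comb, top = 1000)
  grp <- rep(c("T", "N"), times = c(ncol(m$tumor$values),
                                    ncol(m$normal$values)))
  d <- as.matrix(dist(xy3))
  within <- mean(d[grp == "T", grp == "T"]) + mean(d[grp == "N", grp == "N"])
  between <- 2 * mean(d[grp == "T", grp == "N"])
  expect_gt(between, within)
})
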