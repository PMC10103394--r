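test_that("Welch DE matches a per-gene t.test oracle", {
  set.seed(11)
  x <- matrix(rnorm(50 * 9, 6, 1), 50,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("s%d", 1:9)))
  x[3, ] <- 5  # identical in both groups -> t = 0, p = 1
  ex <- expression_matrix(x, "log2")
  ga <- paste0("s", 1:4); gb <- paste0("s", 5:9)
  de <- differential_expression(ex, ga, gb)
  ref <- naive_welch(x, 1:4, 5:9)
  expect_equal(de$t_statistic, unname(ref[, "t"]), tolerance = 1e-10)
  expect_equal(de$p_value, unname(ref[, "p"]), tolerance = 1e-10)
  expect_equal(de$log2_fc, unname(rowMeans(x[, 1:4]) - rowMeans(x[, 5:9])))
  expect_equal(de$t_statistic[3], 0)
  expect_equal(de$p_value[3], 1)
  # q >= p and direction consistency
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  expect_true(all((de$log2_fc >= 0) == (de$direction == "up")))
  # permuting sample order within groups changes nothing
  de2 <- differential_expression(ex, rev(ga), sample(gb))
  expect_equal(de2$t_statistic, de$t_statistic)
  expect_error(differential_expression(ex, ga[1], gb), "at least 2")
  expect_error(differential_expression(ex, ga, c(ga[1], gb[-1])), "disjoint")
})

test_that("BH q-values equal a brute-force implementation on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), naive_bh(p), tolerance = 1e-12)
  }
})

test_that("top-gene selection follows the p / |t| / id ranking", {
  de <- data.frame(
    gene = c("GB", "GA", "GC", "GD", "GE"),
    t_statistic = c(5, -5, 2, 8, -1),
    p_value = c(0.01, 0.01, 0.2, 0.001, 0.5),
    q_value = c(0.02, 0.02, 0.25, 0.005, 0.5),
    log2_fc = c(1, -1, 0.5, 2, -0.1),
    direction = c("up", "down", "up", "up", "down"),
    stringsAsFactors = FALSE)
  class(de) <- c("DEResult", class(de))
  # brute-force sort oracle
  expect_equal(select_top_genes(de, 2), c("GD", "GA"))
  # identical p and |t|: lexicographically smaller id first
  expect_equal(select_top_genes(de, 3), c("GD", "GA", "GB"))
  expect_equal(select_top_genes(de, 2, "up"), c("GD", "GB"))
  expect_setequal(select_top_genes(de, 5), de$gene)
  expect_error(select_top_genes(de, 0), "positive")
  expect_error(select_top_genes(de, 6), "exceeds")
})

test_that("concordant up-regulated genes match set-algebra on random toys", {
  set.seed(5)
  th <- default_thresholds()
  mk <- function() {
    d <- data.frame(
      gene = sprintf("G%02d", 1:50),
      t_statistic = rnorm(50),
      p_value = runif(50),
      q_value = NA_real_,
      log2_fc = rnorm(50, 0, 1),
      stringsAsFactors = FALSE)
    d$q_value <- p.adjust(d$p_value, "BH")
    d$direction <- ifelse(d$log2_fc >= 0, "up", "down")
    class(d) <- c("DEResult", class(d))
    d
  }
  for (i in 1:30) {
    a <- mk(); b <- mk(); n <- sample(5:25, 1)
    res <- concordant_up_genes(a, b, n, th)
    brute <- function(d) {
      up <- d[d$direction == "up", ]
      up <- up[order(up$p_value, -abs(up$t_statistic), up$gene), ]
      sel <- head(up$gene, n)
      intersect(sel, d$gene[d$log2_fc >= log2(1.5)])
    }
    sa <- brute(a); sb <- brute(b)
    expect_setequal(res$genes, intersect(sa, sb))
    expect_equal(unname(res$venn),
                 c(length(setdiff(sa, sb)), length(setdiff(sb, sa)),
                   length(intersect(sa, sb))))
  }
  # identical inputs: everything concordant
  a <- mk()
  res <- concordant_up_genes(a, a, 10)
  expect_equal(unname(res$venn[c("a_only", "b_only")]), c(0, 0))
})

test_that("enrichment percentage is a literal pass-count over the signature", {
  de <- data.frame(
    gene = sprintf("G%02d", 1:10),
    t_statistic = rep(3, 10),
    p_value = rep(0.001, 10),
    q_value = c(rep(0.01, 3), rep(0.5, 7)),
    log2_fc = c(rep(1, 3), rep(1, 4), rep(-1, 3)),
    direction = c(rep("up", 7), rep("down", 3)),
    stringsAsFactors = FALSE)
  class(de) <- c("DEResult", class(de))
  r <- signature_enrichment_percentage(de, de$gene)
  expect_equal(r$percentage, 30)  # 3 of 10 pass q AND fc AND up
  expect_equal(r$n_enriched, 3)
  none <- signature_enrichment_percentage(de, c("G08", "G09", "G10"))
  expect_equal(none$percentage, 0)
  all_pass <- signature_enrichment_percentage(de, c("G01", "G02", "G03"))
  expect_equal(all_pass$percentage, 100)
  expect_error(signature_enrichment_percentage(de, "ABSENT", signature_name = "x"),
               "x")
})

test_that("stage enrichment declines from OPC to MO on synthetic PM cohorts", {
  b <- simulate_bulk_cohort(small_bulk_config(seed = 21))
  nt <- names(b$labels)[b$labels == "NT"]
  stages <- load_stage_signatures()
  for (grp in c("PM_codel", "PM_noncodel")) {
    de <- differential_expression(b$expr, names(b$labels)[b$labels == grp], nt)
    prof <- stage_enrichment_profile(de, stages)
    expect_identical(prof$signature, c("OPC", "COP", "NFOL", "MFOL", "MO"))
    expect_true(all(diff(prof$percentage) <= 0))
    expect_gt(prof$percentage[prof$signature == "OPC"],
              prof$percentage[prof$signature == "MO"])
  }
})
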