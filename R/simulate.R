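#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators, with defaults
#' emulating the study conditions the pipeline assumes: a bulk cohort of
#' non-tumor brain plus PM (IDH-mutant, with/without 1p19q co-deletion) and
#' EM tumor groups carrying stage-graded oligodendrocyte-lineage programs; a
#' single-cell mixture of mostly quiescent malignant OPC/COP-like cells with
#' arm-level CNVs and microglia/oligodendrocyte/T-cell contaminants; and
#' tumor/normal methylomes with hypermethylation concentrated at
#' myelination-gene promoters and hypomethylation at OPC-regulator promoters.
#'
#' @param seed integer seed; every generator is fully deterministic given it.
#' @param n_genes gene-universe size (packaged signature genes plus filler).
#' @param groups named sample counts for the bulk cohort.
#' @param stage_program mean log2 tumor-vs-NT shift per lineage stage for the
#'   genes of that stage's signature; declines monotonically from OPC to MO
#'   in PM tumors (myelination-stage genes are suppressed).
#' @param module_shift log2 up-shift of EM/PM module genes in their subtype.
#' @param gene_effect_sd per-gene SD around the stage/module mean shift.
#' @param dosage_loss_factor multiplicative expression factor for hemizygous
#'   1p/19q loss in bulk tumors (default 0.67, reflecting stromal admixture).
#' @param purity tumor cell fraction of bulk tumor samples; tumor-specific
#'   effects are diluted by linear-scale mixing with the non-tumor profile.
#' @param noise_sd log2-scale Gaussian noise SD for bulk samples.
#' @param baseline_mean,baseline_sd log2 baseline expression distribution.
#' @param sc_cells named cell counts per population for the single-cell
#'   generator (`malignant` plus contaminant populations).
#' @param sc_library_size mean UMIs per cell (log-normal across cells).
#' @param sc_dispersion negative-binomial size parameter.
#' @param prolif_fraction fraction of malignant cells expressing the
#'   proliferation markers (default 0.06).
#' @param sc_cnv named numeric vector of per-arm dosage factors carried by
#'   malignant cells (default hemizygous 1p/19q loss at 0.5; single cells
#'   are pure tumor).
#' @param n_cpgs CpG-universe size for the methylome generator.
#' @param meth_groups named sample counts, `tumor` and `normal`.
#' @param beta_noise_sd per-sample Gaussian noise on beta values (clipped to
#'   \[0, 1\]).
#' @param beta_hyper_delta mean beta increase at hypermethylated CpGs (and
#'   decrease at hypomethylated ones); must be < 1.
#' @param n_dmp_true number of truly differential CpGs.
#' @param hyper_fraction fraction of true DMPs that are hypermethylated
#'   (default 0.96, the hypermethylator phenotype).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000,
                       groups = c(NT = 30, PM_codel = 30, PM_noncodel = 30,
                                  EM = 30),
                       stage_program = c(pre_OPC = 1.8, OPC = 2.0, COP = 1.7,
                                         NFOL = 0.65, MFOL = -1.5, MO = -2.5),
                       module_shift = 2.0,
                       gene_effect_sd = 0.3,
                       dosage_loss_factor = 0.67,
                       purity = 0.8,
                       noise_sd = 0.5,
                       baseline_mean = 7, baseline_sd = 1.5,
                       sc_cells = c(malignant = 500, microglia = 100,
                                    oligodendrocyte = 80, T_cell = 40),
                       sc_library_size = 4000,
                       sc_dispersion = 4,
                       prolif_fraction = 0.06,
                       sc_cnv = c("1p" = 0.5, "19q" = 0.5),
                       n_cpgs = 20000,
                       meth_groups = c(tumor = 20, normal = 20),
                       beta_noise_sd = 0.05,
                       beta_hyper_delta = 0.3,
                       n_dmp_true = 2000,
                       hyper_fraction = 0.96) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1 || any(cfg$groups < 1) || any(cfg$sc_cells < 1) ||
      cfg$n_cpgs < 1 || any(cfg$meth_groups < 1))
    stop("all counts must be >= 1")
  if (!(cfg$dosage_loss_factor > 0 && cfg$dosage_loss_factor < 1))
    stop("dosage_loss_factor must lie in (0, 1)")
  if (cfg$prolif_fraction < 0 || cfg$prolif_fraction > 1)
    stop("prolif_fraction must lie in [0, 1]")
  if (cfg$beta_hyper_delta >= 1 || cfg$beta_hyper_delta < 0)
    stop("beta_hyper_delta must lie in [0, 1)")
  if (cfg$purity <= 0 || cfg$purity > 1)
    stop("purity must lie in (0, 1]")
  class(cfg) <- "SimConfig"
  cfg
}

# Synthetic chromosome table: length and centromere position (bp).
sim_chrom_table <- function() {
  data.frame(
    chrom = c("1", "2", "3", "7", "10", "19"),
    length = c(2.4e8, 2.4e8, 2.0e8, 1.6e8, 1.35e8, 5.9e7),
    cen = c(1.2e8, 9.3e7, 9.1e7, 6.0e7, 4.0e7, 2.6e7),
    stringsAsFactors = FALSE)
}

#' Synthetic gene universe
#'
#' Builds the gene universe shared by the generators: all packaged signature
#' genes (stage signatures, marker panels, EM/PM modules, methylation gene
#' sets, the 1p19q classifier, SOX2) plus random filler symbols up to
#' `n_genes`, each with synthetic coordinates on chromosomes 1, 2, 3, 7, 10
#' and 19. Sixty percent of the classifier genes are placed on arms 1p/19q
#' (alternating); all other genes are spread evenly across chromosomes so
#' that every chromosome supports wide smoothing windows. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `annotation` (a [gene_annotation()]) and `sets` (the
#'   merged [signature_collection()] of all packaged resources).
#' @export
synthetic_gene_universe <- function(config = sim_config()) {
  sets <- c(load_stage_signatures()$sets,
            load_marker_panels()$sets,
            load_em_pm_signatures()$sets,
            load_methylation_gene_sets()$sets,
            load_packaged_1p19q_classifier()$sets)
  named <- unique(c(unlist(sets, use.names = FALSE), "SOX2"))
  if (config$n_genes < length(named) + 50)
    stop("n_genes (", config$n_genes, ") too small for the ",
         length(named), " packaged signature genes plus filler")
  filler <- sprintf("FILLER%04d", seq_len(config$n_genes - length(named)))
  genes <- c(named, filler)
  classifier <- sets$classifier_1p19q
  tab <- sim_chrom_table()
  withr::with_seed(config$seed, {
    chrom <- character(length(genes))
    names(chrom) <- genes
    # classifier genes: 60% on 1p/19q (alternating), the rest elsewhere
    n_arm <- floor(0.6 * length(classifier))
    on_arm <- classifier[seq_len(n_arm)]
    arm_pick <- rep(c("1p", "19q"), length.out = n_arm)
    other_genes <- setdiff(genes, on_arm)
    other_genes <- sample(other_genes)
    chrom[other_genes] <- rep(tab$chrom, length.out = length(other_genes))
    pos <- numeric(length(genes))
    names(pos) <- genes
    for (i in seq_len(nrow(tab))) {
      g <- names(chrom)[chrom == tab$chrom[i]]
      pos[g] <- round(stats::runif(length(g), 1, tab$length[i] - 2000))
    }
    # place the designated classifier genes on the short arm of chr1 or the
    # long arm of chr19
    chr1p <- on_arm[arm_pick == "1p"]
    chrom[chr1p] <- "1"
    pos[chr1p] <- round(stats::runif(length(chr1p), 1,
                                     tab$cen[tab$chrom == "1"] - 2000))
    chr19q <- on_arm[arm_pick == "19q"]
    chrom[chr19q] <- "19"
    pos[chr19q] <- round(stats::runif(length(chr19q),
                                      tab$cen[tab$chrom == "19"] + 1,
                                      tab$length[tab$chrom == "19"] - 2000))
    cen <- stats::setNames(tab$cen, tab$chrom)
    ann <- gene_annotation(data.frame(
      gene_id = genes,
      chrom = unname(chrom),
      arm = ifelse(pos < cen[chrom], "p", "q"),
      start = unname(pos),
      end = unname(pos) + 1500,
      tss = unname(pos),
      stringsAsFactors = FALSE))
    list(annotation = ann, sets = signature_collection(sets))
  })
}

# Per-gene log2 tumor shift for the PM program (stage signatures in stage
# order, then the pre-OPC panel, then remaining PM module genes) and the EM
# program. First-claiming set wins for genes in several sets.
pm_em_shift_vectors <- function(universe, config) {
  sets <- universe$sets$sets
  genes <- universe$annotation$gene_id
  pm <- stats::setNames(numeric(length(genes)), genes)
  assigned <- stats::setNames(logical(length(genes)), genes)
  order_sets <- c("OPC", "COP", "NFOL", "MFOL", "MO", "pre_OPC")
  for (nm in order_sets) {
    mean_shift <- config$stage_program[[nm]]
    g <- setdiff(intersect(sets[[nm]], genes), genes[assigned])
    pm[g] <- mean_shift + stats::rnorm(length(g), 0, config$gene_effect_sd)
    assigned[g] <- TRUE
  }
  g <- setdiff(intersect(sets$PM, genes), genes[assigned])
  pm[g] <- config$module_shift + stats::rnorm(length(g), 0, config$gene_effect_sd)
  em <- stats::setNames(numeric(length(genes)), genes)
  g <- intersect(sets$EM, genes)
  em[g] <- config$module_shift + stats::rnorm(length(g), 0, config$gene_effect_sd)
  list(pm = pm, em = em)
}

#' Simulate a bulk expression cohort
#'
#' Generates a log2-scale bulk cohort over the synthetic gene universe. PM
#' samples carry the stage-graded oligodendrocyte program of
#' `stage_program` (pre-OPC/OPC/COP up, MFOL/MO and myelination genes down)
#' plus the PM module shift; PM_codel samples additionally have every gene
#' on arms 1p/19q multiplied by `dosage_loss_factor` (before noise); EM
#' samples carry the EM module shift with chromosome 7 gain and chromosome
#' 10 loss. Tumor-specific effects are diluted by linear-scale mixing with
#' the non-tumor profile at fraction `purity`, then log2-scale Gaussian
#' noise of SD `noise_sd` is added. Deterministic given `config$seed`.
#'
#' Recognized group names: `NT`, `PM_codel`, `PM_noncodel`, `EM`; at least
#' one tumor group is required (an NT group is optional, e.g. for
#' classification-only cohorts).
#'
#' @param config a [sim_config()].
#' @return List with `expr` ([expression_matrix()]), `labels` (named group
#'   per sample), `truth` (the [signature_collection()] used), `annotation`.
#' @export
simulate_bulk_cohort <- function(config = sim_config()) {
  known <- c("NT", "PM_codel", "PM_noncodel", "EM")
  bad <- setdiff(names(config$groups), known)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (!length(intersect(names(config$groups), setdiff(known, "NT"))))
    stop("groups must include at least one tumor group")
  universe <- synthetic_gene_universe(config)
  ann <- universe$annotation
  genes <- ann$gene_id
  on_1p19q <- arm_label(ann$chrom, ann$arm) %in% c("1p", "19q")
  chr7 <- ann$chrom == "7"
  chr10 <- ann$chrom == "10"
  withr::with_seed(config$seed + 1L, {
    mu <- stats::rnorm(length(genes), config$baseline_mean, config$baseline_sd)
    names(mu) <- genes
    shifts <- pm_em_shift_vectors(universe, config)
    profile_of <- function(group) {
      t <- mu
      if (group %in% c("PM_codel", "PM_noncodel")) {
        t <- t + shifts$pm
        if (group == "PM_codel")
          t[on_1p19q] <- t[on_1p19q] + log2(config$dosage_loss_factor)
      } else if (group == "EM") {
        t <- t + shifts$em
        t[chr7] <- t[chr7] + log2(1.5)
        t[chr10] <- t[chr10] + log2(0.5)
      }
      if (group == "NT") mu
      else log2(config$purity * 2^t + (1 - config$purity) * 2^mu)
    }
    labels <- rep(names(config$groups), config$groups)
    sample_ids <- sprintf("s%03d_%s", seq_along(labels), labels)
    names(labels) <- sample_ids
    vals <- vapply(labels, function(g)
      profile_of(g) + stats::rnorm(length(genes), 0, config$noise_sd),
      numeric(length(genes)))
    rownames(vals) <- genes
    colnames(vals) <- sample_ids
    list(expr = expression_matrix(vals, scale = "log2"),
         labels = labels,
         truth = universe$sets,
         annotation = ann)
  })
}

#' Simulate a single-cell UMI dataset
#'
#' Draws UMI counts from a negative-binomial model with log-normal
#' cell-specific library sizes. Malignant cells over-express SOX2 and the
#' pre-OPC/OPC/COP programs (with weak NFOL and suppressed MFOL/MO
#' expression) and carry the arm-level dosage factors of `config$sc_cnv`; a
#' `prolif_fraction` subset additionally expresses the proliferation markers
#' (quiescent cells have exactly zero expected proliferation-marker
#' expression). Contaminant microglia / oligodendrocyte / T-cell populations
#' express their packaged marker panels. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `counts` (raw-count [expression_matrix()]),
#'   `cell_truth` (`data.frame`: `cell_id`, `cell_type`, `stage`,
#'   `proliferating`, `cnv_arms`), `annotation`, `sets`, and
#'   `reference_profiles` (genes x stages matrix of expected log2-normalized
#'   expression for pure OPC/COP/NFOL/MFOL/MO populations, for
#'   [stage_correlation()]).
#' @export
simulate_single_cell <- function(config = sim_config()) {
  if (config$prolif_fraction > 1) stop("prolif_fraction must be <= 1")
  if (!"malignant" %in% names(config$sc_cells))
    stop("sc_cells must include a 'malignant' population")
  universe <- synthetic_gene_universe(config)
  ann <- universe$annotation
  sets <- universe$sets$sets
  genes <- ann$gene_id
  arms <- arm_label(ann$chrom, ann$arm)
  withr::with_seed(config$seed + 2L, {
    w <- stats::rlnorm(length(genes), 0, 0.4)
    names(w) <- genes
    boost <- function(base, set_names, factors) {
      r <- base
      for (i in seq_along(set_names))
        r[intersect(sets[[set_names[i]]], genes)] <-
          r[intersect(sets[[set_names[i]]], genes)] * factors[i]
      r
    }
    rate_malignant <- boost(w, c("pre_OPC", "OPC", "COP", "NFOL", "MFOL", "MO"),
                            c(4, 8, 6, 1.5, 0.2, 0.2))
    rate_malignant["SOX2"] <- rate_malignant["SOX2"] * 12
    for (a in names(config$sc_cnv))
      rate_malignant[arms == a] <- rate_malignant[arms == a] * config$sc_cnv[[a]]
    rates <- list(
      malignant = rate_malignant,
      microglia = boost(w, "microglia", 10),
      macrophage = boost(w, "macrophage", 10),
      oligodendrocyte = boost(w, c("oligodendrocyte", "MO"), c(10, 8)),
      T_cell = boost(w, "T_cell", 10),
      astrocyte = boost(w, "astrocyte", 10))
    # each contaminant type also carries a broad type-specific expression
    # program (marker panels alone would make cell types differ in only a
    # handful of genes, which no real cell type does)
    filler <- grep("^FILLER", genes, value = TRUE)
    prog_types <- setdiff(names(rates), "malignant")
    for (i in seq_along(prog_types)) {
      idx <- seq.int((i - 1) * 40 + 1, i * 40)
      blk <- filler[idx[idx <= length(filler)]]
      if (length(blk))
        rates[[prog_types[i]]][blk] <- rates[[prog_types[i]]][blk] * 6
    }
    # non-malignant populations barely transcribe SOX2
    for (nm in setdiff(names(rates), "malignant"))
      rates[[nm]]["SOX2"] <- rates[[nm]]["SOX2"] * 0.05
    prolif_genes <- intersect(sets$proliferation, genes)
    bad <- setdiff(names(config$sc_cells), names(rates))
    if (length(bad)) stop("unknown cell population(s): ",
                          paste(bad, collapse = ", "))
    types <- rep(names(config$sc_cells), config$sc_cells)
    n_cells <- length(types)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    n_mal <- sum(types == "malignant")
    prolif <- rep(FALSE, n_cells)
    if (n_mal > 0 && config$prolif_fraction > 0) {
      n_pro <- round(config$prolif_fraction * n_mal)
      prolif[which(types == "malignant")[seq_len(n_pro)]] <- TRUE
    }
    lib <- stats::rlnorm(n_cells, log(config$sc_library_size), 0.3)
    counts <- matrix(0L, length(genes), n_cells,
                     dimnames = list(genes, cell_ids))
    for (j in seq_len(n_cells)) {
      r <- rates[[types[j]]]
      if (types[j] == "malignant") {
        r[prolif_genes] <- if (prolif[j]) w[prolif_genes] * 4 else 0
      }
      p <- r / sum(r)
      counts[, j] <- stats::rnbinom(length(genes), mu = lib[j] * p,
                                    size = config$sc_dispersion)
    }
    cnv_desc <- paste(sprintf("%s:%g", names(config$sc_cnv), config$sc_cnv),
                      collapse = ";")
    cell_truth <- data.frame(
      cell_id = cell_ids,
      cell_type = types,
      stage = ifelse(types == "malignant", "OPC/COP", NA_character_),
      proliferating = prolif,
      cnv_arms = ifelse(types == "malignant", cnv_desc, ""),
      stringsAsFactors = FALSE)
    stages <- c("OPC", "COP", "NFOL", "MFOL", "MO")
    reference_profiles <- vapply(stages, function(st) {
      r <- boost(w, st, 8)
      log2(1 + 1e4 * r / sum(r))
    }, numeric(length(genes)))
    rownames(reference_profiles) <- genes
    list(counts = expression_matrix(counts, scale = "raw_counts"),
         cell_truth = cell_truth,
         annotation = ann,
         sets = universe$sets,
         reference_profiles = reference_profiles)
  })
}

#' Simulate tumor and normal methylome cohorts
#'
#' Builds a CpG universe with two promoter CpGs per annotated gene (at
#' TSS +/- 500 bp) plus random filler CpGs, then draws beta values with
#' per-sample Gaussian noise clipped to \[0, 1\]. The true hypermethylated
#' set contains every promoter CpG of the packaged myelination genes plus
#' random filler CpGs up to `hyper_fraction * n_dmp_true`; the true
#' hypomethylated set contains the promoter CpGs of the OPC-regulator genes
#' plus filler up to the remainder. Hypermethylated CpGs have tumor mean
#' beta shifted up by `beta_hyper_delta` (baseline drawn low so the shift is
#' not clipped); hypomethylated CpGs are shifted down symmetrically.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `tumor`, `normal` ([beta_matrix()] objects), and
#'   `truth` (`hyper`, `hypo` CpG id vectors, disjoint).
#' @export
simulate_methylomes <- function(config = sim_config()) {
  universe <- synthetic_gene_universe(config)
  ann <- universe$annotation
  msets <- universe$sets$sets
  withr::with_seed(config$seed + 3L, {
    prom <- data.frame(
      cpg_id = c(sprintf("cg_%s_1", ann$gene_id), sprintf("cg_%s_2", ann$gene_id)),
      chrom = c(ann$chrom, ann$chrom),
      pos = c(ann$tss - 500, ann$tss + 500),
      stringsAsFactors = FALSE)
    n_fill <- config$n_cpgs - nrow(prom)
    if (n_fill < config$n_dmp_true)
      stop("n_cpgs too small for the requested number of true DMPs")
    tab <- sim_chrom_table()
    fi <- sample.int(nrow(tab), n_fill, replace = TRUE)
    fill <- data.frame(
      cpg_id = sprintf("cg_fill%05d", seq_len(n_fill)),
      chrom = tab$chrom[fi],
      pos = round(stats::runif(n_fill, 1, tab$length[fi])),
      stringsAsFactors = FALSE)
    coords <- rbind(prom, fill)
    prom_of <- function(gset) {
      g <- intersect(gset, ann$gene_id)
      c(sprintf("cg_%s_1", g), sprintf("cg_%s_2", g))
    }
    n_hyper <- round(config$hyper_fraction * config$n_dmp_true)
    n_hypo <- config$n_dmp_true - n_hyper
    hyper <- prom_of(msets$myelination)
    hypo <- prom_of(msets$opc_regulators)
    pool <- sample(fill$cpg_id)
    hyper <- c(hyper, pool[seq_len(max(0, n_hyper - length(hyper)))])
    pool <- setdiff(pool, hyper)
    hypo <- c(hypo, pool[seq_len(max(0, n_hypo - length(hypo)))])
    m <- stats::runif(nrow(coords), 0.05, 0.95)
    names(m) <- coords$cpg_id
    m[hyper] <- stats::runif(length(hyper), 0.10, 0.45)
    m[hypo] <- stats::runif(length(hypo), 0.55, 0.90)
    m_tumor <- m
    m_tumor[hyper] <- m[hyper] + config$beta_hyper_delta
    m_tumor[hypo] <- m[hypo] - config$beta_hyper_delta
    draw <- function(means, n, prefix) {
      v <- vapply(seq_len(n), function(i)
        pmin(1, pmax(0, means + stats::rnorm(length(means), 0,
                                             config$beta_noise_sd))),
        numeric(length(means)))
      rownames(v) <- coords$cpg_id
      colnames(v) <- sprintf("%s%02d", prefix, seq_len(n))
      beta_matrix(v, coords)
    }
    tumor <- draw(m_tumor, config$meth_groups[["tumor"]], "T")
    normal <- draw(m, config$meth_groups[["normal"]], "N")
    list(tumor = tumor, normal = normal,
         truth = list(hyper = hyper, hypo = hypo))
  })
}
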