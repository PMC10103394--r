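---
title: "Methods: staging IDH-mutant gliomas on the oligodendrocyte lineage"
author: "gliostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging IDH-mutant gliomas on the oligodendrocyte lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

IDH-mutant gliomas — the PM (PDGFRA-module) transcriptome subtype, spanning
both astrocytomas (no 1p19q co-deletion) and oligodendrogliomas (1p19q
co-deleted) — resemble early oligodendrocyte-lineage stages (OPC and COP)
and fail to progress through myelination. `gliostage` implements the
computational chain behind that claim as a reusable pipeline:

1. **Bulk tier.** Per-gene Welch t-tests of tumor versus non-tumor (NT)
   brain on log2 expression, top-N gene selection, intersection of the
   up-regulated lists of the two PM subtypes, and the *enrichment
   percentage* of each lineage-stage signature (OPC, COP, NFOL, MFOL, MO):
   the fraction of the signature that is up-regulated with BH q below
   `de_q` and fold change at least `fc_min`. The pipeline's central
   qualitative claim is the monotone decline of these percentages from OPC
   to MO.
2. **Two-tier classification.** A cohort is first split into EM versus PM
   by clustering on the union of the EM/PM module signatures; the PM subset
   is then clustered with the packaged 152-gene 1p19q classifier and the
   two clusters are oriented by gene dosage: hemizygous arm loss lowers the
   mean expression of classifier genes on 1p/19q, so the lower cluster is
   `codel`.
3. **Single-cell tier.** UMI-count QC (cells with fewer than 200
   transcripts, then genes detected in fewer than 3 cells are removed —
   both boundaries inclusive of 200 and 3), library-size normalization,
   variable-feature selection, PCA, Louvain clustering, marker-panel
   typing, malignancy calls (cluster-level SOX2 positivity plus at least
   one arm-level CNV event), the proliferating fraction of malignant cells
   (concomitant detection of MKI67, TOP2A, CCNB2, CDK1), and Pearson
   correlation of cluster profiles against per-stage reference profiles.
4. **Expression CNV.** Reference-centered, clipped, coordinate-ordered and
   moving-average-smoothed log2 expression, summarized per chromosome arm
   and thresholded into gain/loss/neutral calls.
5. **Methylation tier.** Welch t-tests on beta values, BH adjustment, the
   joint DMP filter (q < 0.05 and |Δβ| strictly > 0.20), the
   hypermethylated fraction, promoter-status summaries for myelination
   versus OPC-regulator genes, and classical MDS of the top-1000 most
   variable CpGs.

Statistical assumptions are deliberately plain: approximately Gaussian
log2 bulk expression within groups (Welch variant, so no equal-variance
assumption), beta values treated as approximately Gaussian per CpG at
cohort sample sizes, and independence across genes/CpGs for BH control.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `de_top_n` | 2000 | genes | top-list size for array cohorts; 1000 is conventional for RNA-seq cohorts |
| `fc_min` | 1.5 | linear fold change | enrichment requires log2 FC ≥ log2(1.5) |
| `de_q` | 0.05 | BH FDR | "enriched" = up AND q < 0.05 AND FC ≥ 1.5 |
| `classifier_p` | 1e-16 | p-value | stringency for deriving a new dosage classifier |
| `min_transcripts_per_cell` | 200 | UMIs | cells below are removed (strictly fewer) |
| `min_cells_per_gene` | 3 | cells | genes detected in fewer are removed |
| `n_features` | 500 | genes | variable features before PCA |
| `cnv_clip` | 1.0 / 1.0 / 0.1 | log2 | per-platform per-gene clip bound (STRT-seq, Smart-seq2, 10X) |
| CNV `window` | 101 | genes | moving-average width; large segments only |
| `gain_cut`/`loss_cut` | ±0.2 | log2 | arm-event thresholds; keep the null false-event rate well under 5% |
| `dmp_q` | 0.05 | BH FDR | DMP significance |
| `dmp_delta_beta` | 0.20 | beta | effect-size filter, strict inequality |
| `tss_window` | 1500 | bp | promoter window around the TSS |
| `mds_top_cpgs` | 1000 | CpGs | variance-ranked selection before MDS |

# What the synthetic generators emulate

The generators in `sim_config()` / `simulate_*()` are first-class,
deterministic (integer-seeded) models of the statistical structure the
analysis assumes, and serve as the parameter-recovery oracle for every
downstream module.

* **Bulk** (`simulate_bulk_cohort`): log2-Gaussian baseline (mean 7, SD
  1.5) with per-group programs. PM tumors shift stage-signature genes by a
  stage-graded program (defaults +1.8 pre-OPC, +2.0 OPC, +1.7 COP, +0.65
  NFOL, −1.5 MFOL, −2.5 MO, per-gene SD 0.3) — chosen so enrichment
  percentages span the full range (high at OPC/COP, intermediate at NFOL,
  zero at MFOL/MO) rather than saturating; PM_codel samples multiply every
  1p/19q gene by `dosage_loss_factor` (0.67 — about two-thirds total
  dosage once stromal cells are considered); EM tumors carry the EM module
  plus chromosome 7 gain / 10 loss. Tumor effects are diluted by
  linear-scale mixing with the NT profile at `purity` (default 0.8; tumor
  purity is a free parameter of the model, and the noiseless dosage
  identity log2(f) holds exactly only at purity 1). Noise is Gaussian on
  the log2 scale (SD 0.5), matching the array-style t-testing downstream.
* **Single cell** (`simulate_single_cell`): negative-binomial counts
  (dispersion 4) with log-normal library sizes (mean 4000 UMIs); malignant
  cells over-express SOX2 and the pre-OPC/OPC/COP panels with weak NFOL
  and suppressed MFOL/MO expression, and carry arm-level dosage factors
  (default hemizygous 1p/19q at 0.5 — single cells are pure tumor, unlike
  bulk); a `prolif_fraction` subset (default 0.06) expresses the four
  proliferation markers, quiescent cells have exactly zero expected
  proliferation-marker expression. Contaminant microglia /
  oligodendrocyte / T-cell populations express their packaged panels plus
  a broad type-specific program of filler genes (marker panels alone would
  make cell types differ in only a handful of genes, which no real cell
  type does).
* **Methylomes** (`simulate_methylomes`): two promoter CpGs per gene plus
  intergenic filler; truly hypermethylated CpGs (96% of 2000 true DMPs —
  the hypermethylator phenotype) include every myelination-gene promoter
  CpG and are drawn with low baseline beta (0.10–0.45) so the +0.30 tumor
  shift is not clipped; OPC-regulator promoters are symmetric on the hypo
  side. Per-sample noise is Gaussian (SD 0.05) clipped to [0, 1].

Not emulated: doublets, ambient RNA, batch effects, probe
cross-hybridization, non-promoter regulatory methylation, subclonal CNV
structure, and realistic gene-gene correlation. Passing recovery tests
therefore shows the pipeline correctly inverts its own generative
assumptions — not that those assumptions capture every property of real
cohorts.

# Numerical and design choices

* **Welch everywhere.** The source workflows state only "t-test"; the
  unequal-variance form is the safer default and is used identically for
  expression and beta values (M-values would be a reasonable swap; betas
  are kept for interpretability of the Δβ > 0.20 filter). Genes/CpGs with
  zero variance in both groups are untestable and reported t = 0, p = 1.
* **Ranking tie-breaks.** Top-N selection orders by ascending p, then
  descending |t|, then lexicographic identifier, making every list fully
  deterministic.
* **Two-group clustering.** The conventional recipe (Ward linkage on
  1 − Pearson after median-centering) proved unreliable for the 1p19q
  split at realistic noise: the hemizygous dosage signal (−0.44 log2 after
  purity dilution) is carried by only ~60% of classifier genes, and Ward's
  greedy merges mis-place borderline samples it never revisits. The
  package instead initializes two-group splits on the leading principal
  component of the centered classifier submatrix (1-D k-means seeded at
  the quartiles) and refines to convergence by nearest-centroid Pearson
  reassignment; k > 2 keeps Ward initialization with the same refinement.
  Both stages are deterministic. Orientation refuses to guess when the two
  clusters have identical 1p/19q means (orientation score 0 raises an
  error suggesting reference centroids).
* **Duplicate probes.** Duplicate gene rows collapse by per-gene maximum
  (order-independent; logged). Symbol matching is upper-case exact, no
  alias expansion — aliasing would silently change signature sizes.
  Classifier symbols missing from a dataset (several are legacy
  identifiers) are dropped with a reported count.
* **PC count.** The original workflow's component rule (Seurat's
  jackstraw-style p < 1e-10) is replaced by a deterministic variance rule:
  keep components whose variance exceeds the mean component variance,
  capped at 20, floor 2. The count is returned with the embedding.
* **Positivity floor.** Clusters whose best panel score falls below the
  90th percentile of cluster-label-permutation null scores are left
  `unassigned`; the marker literature gives no floor, and a permutation
  null adapts to each dataset's expression scale.
* **Proliferation call.** "Concomitant expression" is implemented as all
  panel markers detected (> 0) in the cell; the four-gene panel (MKI67,
  TOP2A, CCNB2, CDK1) is the default, the three-gene variant (without
  CCNB2) can be supplied as a custom panel.
* **CNV reading.** The per-platform cutoffs 1.0/1.0/0.1 are implemented as
  the per-gene clip bound applied to reference-centered log2 values — the
  closest well-defined reading of the wrapped tool's parameters; analyses
  in this package use 1.0. Per-cell median re-centering is applied (the
  original does not state this; it protects arm calls against global
  library-composition shifts). Arm thresholds ±0.2 are this package's
  choice, set to keep the false arm-event rate on CNV-free simulations
  well below 5%, and are logged with every run.
* **Δβ reading.** "Methylation difference > 20%" is read as an absolute
  beta difference > 0.20 (the standard reading), strict inequality, not a
  relative change.
* **MDS sign convention.** Classical scaling is sign-canonicalized per
  axis (first sample non-negative) so coordinates are reproducible.
* **Degenerate inputs** raise errors rather than silently returning:
  constant profiles in correlations, empty DMP sets in fraction
  computations, all-cells-removed QC, windows wider than a chromosome,
  orientation ties.

# Problem sizes in the test and acceptance suites

The suites run entirely on synthetic data: classification cohorts of
3 × 30 samples over a 2000-gene universe (20 seeds), single-cell mixtures
of 500 malignant plus ~220 contaminant cells, CNV null panels of 20
seeded simulations at 210 cells each, methylome cohorts of 20 + 20
samples over 20,000 CpGs (50 seeded nulls at 8000 CpGs), and 100–1000
random fixtures per brute-force equivalence check. These sizes were
chosen to give stable Monte-Carlo estimates for the thresholds being
checked while keeping the default suite quick to run.

# Known limitations

* The packaged stage signatures and EM/PM module lists are synthetic
  testing defaults (canonical anchor genes plus simulated filler); real
  analyses must supply published signature files via
  `read_signature_collection()`.
* The 1p19q orientation rule presumes the cohort actually contains both
  codel and non-codel samples; a pure single-status PM cohort will still
  be split in two and oriented by residual dosage noise (the confidence
  field exposes how weak that orientation is).
* Expression CNV is arm/large-segment level only: no breakpoints, no
  subclones, no allele-specific events.
* Methylation analysis is position-level; region-level (DMR) detection
  and array preprocessing (IDAT parsing, normalization) are out of scope —
  the module consumes beta matrices.
* The O/C2 phenomenon (sporadic astrocytic expression within malignant
  OPC/COP-like cells) is reported descriptively via per-cluster astrocyte
  panel scores; no hard subpopulation call is made.
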