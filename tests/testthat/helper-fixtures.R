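# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

# Small bulk simulation config.
small_bulk_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 600,
             groups = c(NT = 10, PM_codel = 10, PM_noncodel = 10, EM = 10),
             ...)
}

# Small single-cell config (universe kept large enough for CNV smoothing).
small_sc_config <- function(seed = 1L,
                            sc_cells = c(malignant = 250, microglia = 60,
                                         oligodendrocyte = 50, T_cell = 30),
                            ...) {
  sim_config(seed = seed, n_genes = 1200, sc_cells = sc_cells, ...)
}

# Tiny log2 ExpressionMatrix from a matrix-like of values.
toy_expr <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = "log2")
}

# Independent (naive) Benjamini-Hochberg implementation used as an oracle.
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# Naive per-gene Welch t via stats::t.test, as the DE oracle.
naive_welch <- function(x, ia, ib) {
  t(apply(x, 1, function(v) {
    if (stats::var(v[ia]) == 0 && stats::var(v[ib]) == 0)
      return(c(t = 0, p = 1))
    ht <- stats::t.test(v[ia], v[ib])
    c(t = unname(ht$statistic), p = ht$p.value)
  }))
}
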