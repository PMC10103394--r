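# Shared numerical helpers.

# Row-wise Welch two-sample t-test on a numeric matrix.
# Returns t, df, p, and the mean difference (a - b) per row. Rows with zero
# variance in both groups get t = 0, p = 1 (no testable dispersion).
row_welch_t <- function(x, idx_a, idx_b) {
  xa <- x[, idx_a, drop = FALSE]
  xb <- x[, idx_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2 || nb < 2) stop("each group needs at least 2 columns")
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  t <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- na + nb - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate] <- 1
  list(t = t, df = df, p = p, diff = diff)
}

# Centered moving average down each column, window truncated at the edges.
# cumsum-based so it is O(n) per column.
moving_average_columns <- function(x, window) {
  n <- nrow(x)
  if (window < 1) stop("window must be >= 1")
  h <- (window - 1) %/% 2
  cs <- apply(x, 2, cumsum)
  if (n == 1) cs <- matrix(cs, nrow = 1, dimnames = dimnames(x))
  cs <- rbind(0, cs)
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  dimnames(out) <- dimnames(x)
  out
}

# Dense numeric matrix from an ExpressionMatrix (sparse-backed or not).
as_dense_values <- function(expr) {
  v <- expr$values
  if (inherits(v, "Matrix")) v <- as.matrix(v)
  v
}

# Normalized chromosome label without a "chr" prefix.
strip_chr <- function(x) sub("^chr", "", as.character(x))

# Chromosome-arm label, e.g. "1p", "19q".
arm_label <- function(chrom, arm) paste0(strip_chr(chrom), arm)
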