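## Brute-force oracles and fixture builders shared across test files.
## Oracles are literal renderings of the score definitions, independent of
## the vectorized kernels they check.

## relative simplicity evaluated cell by cell from the defining formulas
rs_oracle <- function(tab) {
  xl <- function(num, den) if (num > 0) num * log2(num / den) else 0
  f_p <- sum(tab[1, ]); f_m <- sum(tab[2, ])
  n <- f_p + f_m; r <- ncol(tab)
  c_row <- 0
  for (d in seq_len(r)) c_row <- c_row - xl(tab[1, d], f_p)
  for (d in seq_len(r)) c_row <- c_row - xl(tab[2, d], f_m)
  c_col <- 0
  for (d in seq_len(r)) {
    fd <- tab[1, d] + tab[2, d]
    c_col <- c_col - xl(tab[1, d], fd) - xl(tab[2, d], fd)
  }
  c_max <- n * log2(r) + (-xl(f_p, n) - xl(f_m, n))
  if (c_max <= 0) return(0)
  (c_max - (c_row + c_col)) / c_max
}

## literal double-loop integrated ranking over the scalar table path
irs_oracle <- function(task) {
  genes <- colnames(task$values)
  p <- length(genes)
  rs_i <- vapply(genes, function(g) rs_individual(task, g), numeric(1))
  P <- matrix(0, p, p)
  for (j in seq_len(p)) for (q in seq_len(p)) if (j != q)
    P[j, q] <- rs_pair(task, genes[j], genes[q])$score
  irs <- numeric(p)
  for (j in seq_len(p)) {
    acc <- rs_i[j]
    for (q in seq_len(p)) if (q != j) {
      w <- if (rs_i[j] + rs_i[q] > 0) rs_i[j] / (rs_i[j] + rs_i[q]) else 0
      acc <- acc + w * P[j, q]
    }
    irs[j] <- acc
  }
  names(irs) <- genes
  irs
}

## random non-degenerate 2 x r count table (integers, optionally with .5s)
random_table <- function(r = 2, max_count = 12, halves = FALSE) {
  repeat {
    tab <- matrix(sample(0:max_count, 2 * r, replace = TRUE), 2, r)
    if (halves) tab <- tab + matrix(sample(c(0, 0.5), 2 * r, TRUE), 2, r)
    if (sum(tab[1, ]) > 0 && sum(tab[2, ]) > 0) return(tab)
  }
}

## small random labeled dataset (balanced binary unless told otherwise)
random_dataset <- function(n = 8, p = 5, classes = c("a", "b")) {
  labels <- rep_len(classes, n)
  expression_dataset(matrix(round(stats::rnorm(n * p, 100, 25), 3), n, p),
                     labels = labels)
}

## fixture chi-square convention for vertical pair tables: drop
## zero-total columns, corrected 2x2 if two columns remain, else Pearson
chi2_collapsed <- function(tab) {
  red <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(red) == 2L) chi2_2x2_corrected(red)$statistic
  else chi2_2xr_pearson(red)$statistic
}
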