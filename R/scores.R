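## Scalar scores of 2 x r contingency tables: Shannon entropy, complexity,
## maximum complexity, relative simplicity, and two chi-square statistics.
## All logarithms are base 2; every 0 * log(0/x) term is defined as 0.

## n * log2(n / d) with the 0-count convention; vectorized, d recycled
.xlog2 <- function(num, den) {
  out <- num
  pos <- num > 0
  out[pos] <- num[pos] * log2(num[pos] / den[pos])
  out
}

.check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("contingency table must have 2 rows")
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  tab
}

#' Shannon entropy of a count vector (bits)
#'
#' `H = -sum (n_i/N) log2(n_i/N)`.  Entropy only sees the event ratios:
#' multiplying all counts by a constant leaves it unchanged, which is
#' exactly the information the complexity score retains and entropy drops.
#'
#' @param counts Non-negative numeric vector with a positive sum.
#' @return Entropy in bits.
#' @examples
#' entropy_bits(c(3, 7))    # 0.8813
#' entropy_bits(c(30, 70))  # identical
#' @export
entropy_bits <- function(counts) {
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("at least one positive count is required")
  -sum(.xlog2(counts / n, rep(1, length(counts))))
}

## strict left-to-right double-precision accumulation (sum() carries
## extended-precision intermediates, which would make the scalar path
## differ from the vectorized kernels by an ulp on r = 4 tables)
.dsum <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v
  acc
}

#' Complexity of a 2 x r contingency table (bits)
#'
#' Complexity is the frequency-weighted analogue of entropy,
#' `C = -sum n_i log2(n_i/N)`, accumulated over the rows and the columns of
#' the table: `C = C_row + C_column`.  Unlike entropy it grows with absolute
#' counts, so tables backed by more samples carry more weight.
#'
#' @param tab A 2 x r non-negative matrix (rows: +, -).  Half-integer counts
#'   from tie splitting are fine.
#' @return List with `C_row`, `C_column` and `C = C_row + C_column`.
#' @export
complexity <- function(tab) {
  tab <- .check_table(tab)
  f_p <- sum(tab[1L, ]); f_m <- sum(tab[2L, ])
  f_d <- tab[1L, ] + tab[2L, ]
  c_row <- -(.dsum(.xlog2(tab[1L, ], rep(f_p, ncol(tab)))) +
             .dsum(.xlog2(tab[2L, ], rep(f_m, ncol(tab)))))
  c_col <- -.dsum(.xlog2(tab[1L, ], f_d) + .xlog2(tab[2L, ], f_d))
  list(C_row = c_row, C_column = c_col, C = c_row + c_col)
}

#' Maximum complexity of a 2 x r contingency table (bits)
#'
#' Complexity of the table with the same class margins but the counts of
#' each class spread evenly over the r columns: `C_row_max = n log2(r)` and
#' `C_column_max = -f_+ log2(f_+/n) - f_- log2(f_-/n)`.  Dividing by it
#' makes tables with different column counts comparable.
#'
#' @inheritParams complexity
#' @return List with `C_row_max`, `C_column_max` and `C_max`.
#' @export
max_complexity <- function(tab) {
  tab <- .check_table(tab)
  n <- sum(tab)
  f_p <- sum(tab[1L, ]); f_m <- sum(tab[2L, ])
  c_row_max <- n * log2(ncol(tab))
  c_col_max <- -(.xlog2(f_p, n) + .xlog2(f_m, n))
  list(C_row_max = c_row_max, C_column_max = c_col_max,
       C_max = c_row_max + c_col_max)
}

#' Relative simplicity of a 2 x r contingency table
#'
#' `RS = (C_max - C) / C_max`, a dimensionless score in `[0, 1]`: 1 for a
#' perfectly class-separating (pure-column) table, 0 for a table that
#' already has maximal complexity (columns proportional within each class).
#' The degenerate case `C_max = 0` is defined as 0.
#'
#' @inheritParams complexity
#' @return RS in `[0, 1]`.
#' @examples
#' relative_simplicity(rbind(c(4, 0), c(0, 4)))  # 1
#' relative_simplicity(rbind(c(2, 2), c(2, 2)))  # 0
#' @export
relative_simplicity <- function(tab) {
  cmax <- max_complexity(tab)$C_max
  if (cmax <= 0) return(0)
  (cmax - complexity(tab)$C) / cmax
}

#' Entropy-based simplicity of a 2 x r contingency table
#'
#' Comparator score for the entropy backend: the same
#' `(max - observed) / max` construction as relative simplicity, but with
#' each row's and column's Shannon entropy in place of its complexity, i.e.
#' with the frequency weighting dropped.  `H_row_max` is `log2(r)` per
#' non-empty class row; `H_column_max` is r times the entropy of the class
#' margin split.
#'
#' @inheritParams complexity
#' @return Score in `[0, 1]`; 0 when the maximum entropy is 0.
#' @export
entropy_simplicity <- function(tab) {
  tab <- .check_table(tab)
  n <- sum(tab)
  if (n <= 0) return(0)
  r <- ncol(tab)
  f_p <- sum(tab[1L, ]); f_m <- sum(tab[2L, ])
  f_d <- tab[1L, ] + tab[2L, ]
  h_row <- (if (f_p > 0) entropy_bits(tab[1L, ]) else 0) +
           (if (f_m > 0) entropy_bits(tab[2L, ]) else 0)
  h_col <- sum(vapply(seq_len(r), function(d)
    if (f_d[d] > 0) entropy_bits(tab[, d]) else 0, numeric(1)))
  h_row_max <- ((f_p > 0) + (f_m > 0)) * log2(r)
  h_col_max <- r * entropy_bits(c(f_p, f_m))
  h_max <- h_row_max + h_col_max
  if (h_max <= 0) return(0)
  (h_max - (h_row + h_col)) / h_max
}

#' Continuity-corrected chi-square for a 2x2 table
#'
#' `chi2 = n (|ad - bc| - n/2)^2 / (f_+ f_- f_1 f_2)`.  The default variant
#' (`"yates_nofloor"`) does not floor the corrected term `|ad - bc| - n/2`
#' at zero before squaring; `"yates"` floors it, `"none"` omits the
#' correction (plain Pearson).  A table with any zero margin scores 0.
#'
#' @param tab A 2 x 2 non-negative matrix.
#' @param correction `"yates_nofloor"` (default), `"yates"` or `"none"`.
#' @return List with `statistic` and `p_value` (upper tail, 1 df).
#' @examples
#' chi2_2x2_corrected(rbind(c(4, 0), c(0, 4)))$statistic  # 4.5
#' chi2_2x2_corrected(rbind(c(2, 2), c(2, 2)))$statistic  # 0.5
#' @export
chi2_2x2_corrected <- function(tab,
                               correction = c("yates_nofloor", "yates",
                                              "none")) {
  correction <- match.arg(correction)
  tab <- .check_table(tab)
  if (ncol(tab) != 2L) stop("table must be 2 x 2")
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  n <- a + b + c_ + d
  f_p <- a + b; f_m <- c_ + d; f_1 <- a + c_; f_2 <- b + d
  if (any(c(f_p, f_m, f_1, f_2) == 0))
    return(list(statistic = 0, p_value = 1))
  term <- switch(correction,
                 yates_nofloor = abs(a * d - b * c_) - n / 2,
                 yates = max(abs(a * d - b * c_) - n / 2, 0),
                 none = abs(a * d - b * c_))
  stat <- n * term^2 / (f_p * f_m * f_1 * f_2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pearson chi-square for a 2 x r table
#'
#' Uncorrected `sum (O - E)^2 / E` over cells with positive expected count,
#' expectations from the row/column margins, `df = r - 1`.
#'
#' @inheritParams complexity
#' @return List with `statistic`, `df` and `p_value`.
#' @examples
#' chi2_2xr_pearson(rbind(c(2, 0, 0, 2), c(0, 2, 2, 0)))$statistic  # 8
#' @export
chi2_2xr_pearson <- function(tab) {
  tab <- .check_table(tab)
  if (ncol(tab) < 2L) stop("table must have at least 2 columns")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  keep <- expected > 0
  stat <- sum((tab[keep] - expected[keep])^2 / expected[keep])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Score backend dispatch
#'
#' Maps a backend name to a scalar score function over a contingency table:
#' `"rs"` is [relative_simplicity()]; `"entropy"` is [entropy_simplicity()];
#' `"chi2"` uses the corrected 2x2 statistic ([chi2_2x2_corrected()]) for
#' two-column tables and the plain Pearson statistic ([chi2_2xr_pearson()])
#' otherwise.  The backends are drop-in comparators: the whole
#' ranking/selection/classification pipeline accepts any of them.
#'
#' @param name `"rs"`, `"entropy"` or `"chi2"`.
#' @param correction Correction variant passed to [chi2_2x2_corrected()].
#' @return A function `f(tab) -> scalar score` (larger = more informative).
#' @export
score_backend <- function(name = c("rs", "entropy", "chi2"),
                          correction = "yates_nofloor") {
  name <- match.arg(name)
  switch(name,
         rs = relative_simplicity,
         entropy = entropy_simplicity,
         chi2 = function(tab) {
           if (ncol(as.matrix(tab)) == 2L)
             chi2_2x2_corrected(tab, correction)$statistic
           else chi2_2xr_pearson(tab)$statistic
         })
}
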