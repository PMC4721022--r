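#' Individual-gene score under the vertical comparison
#'
#' Relative simplicity (or the configured backend's score) of the gene's
#' 2x2 endpoint table: [individual_table()] scored by [score_backend()].
#'
#' @param task A [binary_task()].
#' @param gene Gene id.
#' @param backend,correction Score backend, see [score_backend()].
#' @return Scalar score.
#' @export
rs_individual <- function(task, gene, backend = "rs",
                          correction = "yates_nofloor") {
  score_backend(backend, correction)(
    individual_table(task, gene, endpoint(task, gene)))
}

#' Pair-wise gene score combining horizontal and vertical comparisons
#'
#' For the RS backend the pair score pools the complexities of the
#' horizontal 2x2 table and the vertical 2x4 table before normalizing:
#' `RS_pair = ((C_hor_max + C_ver_max) - (C_hor + C_ver)) /
#' (C_hor_max + C_ver_max)`, which is symmetric in the two genes and lies in
#' `[0, 1]`.  The entropy backend applies the same pooling to the
#' entropy decomposition; the chi2 backend returns the sum of the corrected
#' 2x2 statistic (horizontal) and the Pearson 2x4 statistic (vertical).
#'
#' @inheritParams rs_individual
#' @param gene_j,gene_q Distinct gene ids.
#' @return A list with the horizontal and vertical components and the
#'   combined `score`.
#' @export
rs_pair <- function(task, gene_j, gene_q, backend = "rs",
                    correction = "yates_nofloor") {
  if (identical(gene_j, gene_q)) stop("gene_j and gene_q must differ")
  hor <- horizontal_pair_table(task, gene_j, gene_q)
  ver <- vertical_pair_table(task, gene_j, gene_q)
  if (backend == "rs") {
    c_hor <- complexity(hor)$C;  c_hor_max <- max_complexity(hor)$C_max
    c_ver <- complexity(ver)$C;  c_ver_max <- max_complexity(ver)$C_max
    denom <- c_hor_max + c_ver_max
    score <- if (denom <= 0) 0 else (denom - (c_hor + c_ver)) / denom
    list(C_hor = c_hor, C_hor_max = c_hor_max,
         C_ver = c_ver, C_ver_max = c_ver_max, score = score)
  } else if (backend == "entropy") {
    hh <- .entropy_parts(hor); hv <- .entropy_parts(ver)
    denom <- hh$h_max + hv$h_max
    score <- if (denom <= 0) 0 else (denom - (hh$h + hv$h)) / denom
    list(H_hor = hh$h, H_hor_max = hh$h_max,
         H_ver = hv$h, H_ver_max = hv$h_max, score = score)
  } else {
    s_hor <- chi2_2x2_corrected(hor, correction)$statistic
    s_ver <- chi2_2xr_pearson(ver)$statistic
    list(chi2_hor = s_hor, chi2_ver = s_ver, score = s_hor + s_ver)
  }
}

## observed and maximum row+column entropies of a 2 x r table
.entropy_parts <- function(tab) {
  tab <- .check_table(tab)
  r <- ncol(tab)
  f_p <- sum(tab[1L, ]); f_m <- sum(tab[2L, ])
  f_d <- tab[1L, ] + tab[2L, ]
  h <- (if (f_p > 0) entropy_bits(tab[1L, ]) else 0) +
       (if (f_m > 0) entropy_bits(tab[2L, ]) else 0) +
       sum(vapply(seq_len(r), function(d)
         if (f_d[d] > 0) entropy_bits(tab[, d]) else 0, numeric(1)))
  h_max <- ((f_p > 0) + (f_m > 0)) * log2(r) +
           r * (if (f_p > 0 || f_m > 0) entropy_bits(c(f_p, f_m)) else 0)
  list(h = h, h_max = h_max)
}

#' Integrated gene ranking
#'
#' Ranks all genes of a binary task by the integrated score: the gene's own
#' vertical score plus, for every other gene q, its weighted share of the
#' pair score, `IRS_j = s_j + sum_q s_j / (s_j + s_q) * s_pair(j, q)`.
#' The weight splits each pair's credit between the two partners in
#' proportion to their individual scores; a `0/0` weight (both genes
#' individually uninformative) contributes nothing to either gene.  The sum
#' runs over all `p - 1` partners, so ranking costs `O(p^2)` pair
#' evaluations, all computed by vectorized kernels.  Ties are broken by
#' original gene order.
#'
#' @inheritParams rs_individual
#' @return An object of class `gene_ranking`: a data frame with columns
#'   `gene`, `rs_individual`, `irs` and `rank`, sorted by descending
#'   integrated score, with the backend name in attribute `backend`.
#' @examples
#' task <- binary_task(pattern_fixture(), "+")
#' head(integrated_rank(task))
#' @export
integrated_rank <- function(task, backend = "rs",
                            correction = "yates_nofloor") {
  stopifnot(inherits(task, "binary_task"))
  if (ncol(task$values) < 2L) stop("ranking needs at least 2 genes")
  k <- .kernel_integrated(task$values, task$pos, backend, correction)
  ord <- order(-k$integrated)   # stable: ties keep original gene order
  df <- data.frame(gene = colnames(task$values)[ord],
                   rs_individual = k$individual[ord],
                   irs = k$integrated[ord],
                   rank = seq_along(ord),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, backend = backend, class = c("gene_ranking", "data.frame"))
}
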