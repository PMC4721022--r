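## Contingency-table construction.  Every score in this package is a
## function of a 2 x r real-valued count table (rows: +, -).  Exact ties
## split a sample's unit mass 0.5/0.5 between the two columns of its class
## row, so counts may be half-integers; grand totals are always conserved.

## weight of each value on the ">" side of a threshold: 1 above, 0 below,
## 0.5 on an exact tie
.gt_weight <- function(x, threshold) {
  (x > threshold) + 0.5 * (x == threshold)
}

.task_gene <- function(task, gene) {
  stopifnot(inherits(task, "binary_task"))
  if (is.character(gene) && !gene %in% colnames(task$values))
    stop("unknown gene id: ", gene)
  task$values[, gene]
}

#' Endpoint (binarization threshold) of a gene
#'
#' The per-gene threshold used by all vertical comparisons: the arithmetic
#' mean of the two class means, i.e. the midpoint of the negative-class and
#' positive-class average expression.
#'
#' @param task A [binary_task()].
#' @param gene Gene id (or column index).
#' @return The endpoint, in expression units.
#' @examples
#' fx <- pattern_fixture()
#' endpoint(binary_task(fx, "+"), "G1")  # 75
#' @export
endpoint <- function(task, gene) {
  x <- .task_gene(task, gene)
  (sum(x[!task$pos]) / sum(!task$pos) + sum(x[task$pos]) / sum(task$pos)) / 2
}

.ct <- function(counts, col_names) {
  dimnames(counts) <- list(c("+", "-"), col_names)
  counts
}

#' Vertical 2x2 contingency table of an individual gene
#'
#' Cross-tabulates class against the gene's expression being above or below
#' its endpoint.  Column 1 counts values above `ep`, column 2 values below;
#' a value exactly equal to `ep` contributes 0.5 to both columns of its
#' class row.
#'
#' @inheritParams endpoint
#' @param ep Endpoint; defaults to [endpoint()] of the gene.
#' @return A 2 x 2 numeric matrix, rows `+`/`-`, columns `>EP` / `<EP`.
#' @export
individual_table <- function(task, gene, ep = endpoint(task, gene)) {
  stopifnot(is.finite(ep))
  w <- .gt_weight(.task_gene(task, gene), ep)
  f_p1 <- sum(w[task$pos]); f_m1 <- sum(w[!task$pos])
  .ct(rbind(c(f_p1, sum(task$pos) - f_p1),
            c(f_m1, sum(!task$pos) - f_m1)),
      c(">EP", "<EP"))
}

#' Horizontal 2x2 contingency table of a gene pair
#'
#' Cross-tabulates class against the within-sample order relation between
#' two genes: column 1 counts samples with `X[, gene_j] > X[, gene_q]`,
#' column 2 the reverse; a within-sample tie contributes 0.5 to both columns
#' of the class row.  Comparing expression within a sample cancels
#' per-sample background shifts, which is what makes this view sensitive to
#' heterogeneous-background gene pairs invisible to any per-gene threshold.
#'
#' @inheritParams endpoint
#' @param gene_j,gene_q Distinct gene ids.
#' @return A 2 x 2 numeric matrix, rows `+`/`-`, columns `j>q` / `j<q`.
#' @export
horizontal_pair_table <- function(task, gene_j, gene_q) {
  if (identical(gene_j, gene_q)) stop("gene_j and gene_q must differ")
  w <- .gt_weight(.task_gene(task, gene_j), .task_gene(task, gene_q))
  f_p1 <- sum(w[task$pos]); f_m1 <- sum(w[!task$pos])
  .ct(rbind(c(f_p1, sum(task$pos) - f_p1),
            c(f_m1, sum(!task$pos) - f_m1)),
      c("j>q", "j<q"))
}

#' Vertical 2x4 contingency table of a gene pair
#'
#' Cross-tabulates class against the joint endpoint split of two genes, with
#' columns in the order (>,>), (>,<), (<,>), (<,<) relative to
#' `(ep_j, ep_q)`.  A tie on one gene splits the sample 0.5/0.5 across the
#' two columns consistent with the other gene; a tie on both genes splits it
#' 0.25 four ways.
#'
#' @inheritParams horizontal_pair_table
#' @param ep_j,ep_q Endpoints of the two genes; default to [endpoint()].
#' @return A 2 x 4 numeric matrix, rows `+`/`-`.
#' @export
vertical_pair_table <- function(task, gene_j, gene_q,
                                ep_j = endpoint(task, gene_j),
                                ep_q = endpoint(task, gene_q)) {
  if (identical(gene_j, gene_q)) stop("gene_j and gene_q must differ")
  aj <- .gt_weight(.task_gene(task, gene_j), ep_j)
  aq <- .gt_weight(.task_gene(task, gene_q), ep_q)
  cols <- cbind(aj * aq, aj * (1 - aq), (1 - aj) * aq, (1 - aj) * (1 - aq))
  .ct(rbind(colSums(cols[task$pos, , drop = FALSE]),
            colSums(cols[!task$pos, , drop = FALSE])),
      c(">,>", ">,<", "<,>", "<,<"))
}
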