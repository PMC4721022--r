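#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`, defined as
#' 0 when any marginal factor is zero.
#'
#' @param tp,tn,fp,fn Confusion counts (true/false positives/negatives).
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(4, 3, 1, 2)  # 10 / sqrt(600)
#' @export
mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fn * fp) / sqrt(den)
}

## score of a gene subset on an explicit matrix + label assignment:
## individual score for a single gene, network score for two or more
.subset_score <- function(X, pos, backend = "rs",
                          correction = "yates_nofloor") {
  if (ncol(X) == 1L)
    .kernel_individual(X, pos, backend, correction)[1L]
  else
    sum(.kernel_pair(X, pos, backend, correction))
}

#' Network score of a gene subset
#'
#' Sum of the pair scores over all ordered pairs of distinct genes in the
#' subset (each unordered pair counted twice), computed on the task's data
#' with endpoints taken from the data as labeled -- so reassigning one
#' sample's label changes every endpoint and every count, which is exactly
#' what the transductive classifier exploits.
#'
#' @param task A [binary_task()].
#' @param genes Character vector of at least 2 gene ids.
#' @param backend,correction See [score_backend()].
#' @return Scalar network score.
#' @export
rs_net <- function(task, genes, backend = "rs",
                   correction = "yates_nofloor") {
  stopifnot(inherits(task, "binary_task"))
  if (length(genes) < 2L) stop("rs_net needs at least 2 genes")
  sum(.kernel_pair(task$values[, genes, drop = FALSE], task$pos,
                   backend, correction))
}

#' Transductive binary direct classification of one sample
#'
#' Parameter-free prediction: append the query sample to the training data,
#' assign it the positive label and score the gene subset on the merged,
#' relabeled data; then assign the negative label and score again.  The
#' sample is called positive iff the positive assignment scores strictly
#' higher; ties go to the negative class.  Endpoints and all contingency
#' tables are recomputed on the merged data under each assignment; outlier
#' adjustment is never re-run on the merged data.  With a single gene the
#' comparison uses the individual vertical score, otherwise the network
#' score [rs_net()].
#'
#' @param task A [binary_task()] holding the training data.
#' @param sample Named numeric vector with a value for every gene in
#'   `genes`.
#' @param genes Non-empty character vector of gene ids.
#' @inheritParams rs_net
#' @return List with `score_pos`, `score_neg` and `predicted` (`"+"` or
#'   `"-"`).
#' @export
dc_predict_binary <- function(task, sample, genes, backend = "rs",
                              correction = "yates_nofloor") {
  stopifnot(inherits(task, "binary_task"), length(genes) >= 1L)
  if (!all(genes %in% colnames(task$values)))
    stop("unknown gene ids: ",
         paste(setdiff(genes, colnames(task$values)), collapse = ", "))
  sv <- if (is.null(names(sample))) {
    if (length(sample) != length(genes))
      stop("unnamed sample vector must have one value per gene")
    sample
  } else sample[genes]
  if (anyNA(sv))
    stop("sample is missing values for: ",
         paste(genes[is.na(sv)], collapse = ", "))
  Xm <- rbind(task$values[, genes, drop = FALSE],
              matrix(sv, 1L, dimnames = list("query", genes)))
  s_pos <- .subset_score(Xm, c(task$pos, TRUE), backend, correction)
  s_neg <- .subset_score(Xm, c(task$pos, FALSE), backend, correction)
  list(score_pos = s_pos, score_neg = s_neg,
       predicted = if (s_pos > s_neg) "+" else "-")
}

## leave-one-out transductive predictions of the training samples
## themselves: sample i keeps its row but has its label assigned to + and -
## in turn (the "merge validation back before scoring" scheme)
.loocv_mcc <- function(X, pos, backend, correction) {
  n <- nrow(X)
  pred <- logical(n)
  for (i in seq_len(n)) {
    s_pos <- .subset_score(X, replace(pos, i, TRUE), backend, correction)
    s_neg <- .subset_score(X, replace(pos, i, FALSE), backend, correction)
    pred[i] <- s_pos > s_neg
  }
  mcc(sum(pred & pos), sum(!pred & !pos),
      sum(pred & !pos), sum(!pred & pos))
}

#' Forward informative-gene selection
#'
#' Scans the top `B` ranked genes in order.  The first gene is introduced
#' unconditionally and its leave-one-out MCC becomes the benchmark; each
#' later candidate is added to the current subset, the subset's
#' leave-one-out transductive MCC is recomputed, and the candidate is kept
#' only if it strictly improves the benchmark (which is therefore
#' non-decreasing).  The returned subset is the task's
#' binary-discriminative informative gene (BDIG) set.
#'
#' @param task A [binary_task()].
#' @param ranking A `gene_ranking` from [integrated_rank()] (or a character
#'   vector of gene ids in rank order); computed on the fly if `NULL`.
#' @param B Scan bound: number of top-ranked genes examined (default 100).
#' @inheritParams rs_net
#' @return An object of class `selection_state`: list with `selected`
#'   (ordered gene ids), `benchmark` (final LOOCV MCC) and `trace` (data
#'   frame with one row per candidate: gene, mcc, kept).
#' @export
forward_select <- function(task, ranking = NULL, B = 100L, backend = "rs",
                           correction = "yates_nofloor") {
  stopifnot(inherits(task, "binary_task"))
  if (is.null(ranking)) ranking <- integrated_rank(task, backend, correction)
  ranked <- if (inherits(ranking, "gene_ranking")) ranking$gene
            else as.character(ranking)
  scan <- ranked[seq_len(min(B, length(ranked)))]
  selected <- character()
  benchmark <- -Inf
  trace <- vector("list", length(scan))
  for (j in seq_along(scan)) {
    cand <- c(selected, scan[j])
    m <- .loocv_mcc(task$values[, cand, drop = FALSE], task$pos,
                    backend, correction)
    keep <- if (length(selected) == 0L) TRUE else m > benchmark
    if (keep) {
      selected <- cand
      benchmark <- m
    }
    trace[[j]] <- data.frame(gene = scan[j], mcc = m, kept = keep,
                             stringsAsFactors = FALSE)
  }
  structure(list(selected = selected, benchmark = benchmark,
                 trace = do.call(rbind, trace), B = as.integer(B)),
            class = "selection_state")
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("selection_state: %d informative genes, LOOCV MCC = %.4f\n",
              length(x$selected), x$benchmark))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
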