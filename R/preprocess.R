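#' Adjust outlying expression values gene by gene
#'
#' For every gene independently, values falling outside the band
#' `mean +/- u_alpha * sd` (both statistics over all n training values of
#' that gene) are replaced by `loo_mean +/- u_alpha * loo_sd`, where the
#' leave-one-out statistics exclude the offending value and the sign matches
#' the violated bound.  The band is computed once from the original values;
#' replacements never cascade.  A constant gene (sd = 0) has no outliers.
#' Adjustment is a training-set-only step: test samples are never touched.
#'
#' @param dataset An [expression_dataset()] with at least 3 samples.
#' @param config An [rs_config()]; uses `alpha`/`u_alpha` and `sd_estimator`.
#' @return A list with `dataset` (adjusted copy, same shape, ids and labels)
#'   and `report`, a data frame with one row per replaced cell: sample, gene,
#'   original value, gene mean/sd, leave-one-out mean/sd and the replacement.
#' @examples
#' d <- expression_dataset(cbind(g = c(10, 10, 10, 10, 10, 10, 10, 10, 10, 50)),
#'                         labels = rep(c("a", "b"), 5))
#' adjust_outliers(d)$report
#' @export
adjust_outliers <- function(dataset, config = rs_config()) {
  validate_dataset(dataset)
  v <- dataset$values
  n <- nrow(v)
  if (n < 3L) stop("outlier adjustment needs at least 3 samples")
  u <- config$u_alpha
  pop <- identical(config$sd_estimator, "population")
  sd_fun <- if (pop) function(x) sqrt(mean((x - mean(x))^2)) else stats::sd
  rep_rows <- list()
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    mu <- mean(x)
    s <- sd_fun(x)
    if (s == 0) next
    lo <- mu - u * s
    hi <- mu + u * s
    out <- which(x < lo | x > hi)
    for (i in out) {
      loo <- x[-i]
      loo_mu <- mean(loo)
      loo_sd <- sd_fun(loo)
      new <- if (x[i] < lo) loo_mu - u * loo_sd else loo_mu + u * loo_sd
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        sample = rownames(v)[i], gene = colnames(v)[j],
        original = x[i], gene_mean = mu, gene_sd = s,
        loo_mean = loo_mu, loo_sd = loo_sd, replacement = new,
        stringsAsFactors = FALSE)
      v[i, j] <- new
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(sample = character(), gene = character(), original = numeric(),
               gene_mean = numeric(), gene_sd = numeric(),
               loo_mean = numeric(), loo_sd = numeric(),
               replacement = numeric(), stringsAsFactors = FALSE)
  adjusted <- dataset
  adjusted$values <- v
  list(dataset = adjusted, report = report)
}

#' One-vs-rest binary task
#'
#' @param dataset An [expression_dataset()].
#' @param positive_class Class treated as the positive group `{+}`; all other
#'   samples form the negative group `{-}`.
#' @return A `binary_task`: list with `values` (the full matrix), `pos`
#'   (logical vector, TRUE for positives) and `positive_class`.
#' @export
binary_task <- function(dataset, positive_class) {
  validate_dataset(dataset)
  pos <- dataset$labels == positive_class
  if (!any(pos)) stop("class '", positive_class, "' has no samples")
  if (all(pos)) stop("class '", positive_class, "' covers every sample")
  structure(list(values = dataset$values, pos = pos,
                 positive_class = as.character(positive_class)),
            class = "binary_task")
}

#' @export
print.binary_task <- function(x, ...) {
  cat(sprintf("binary_task: '%s' (+, %d samples) vs rest (-, %d samples), %d genes\n",
              x$positive_class, sum(x$pos), sum(!x$pos), ncol(x$values)))
  invisible(x)
}

#' One-vs-rest decomposition of a multi-class dataset
#'
#' Produces one [binary_task()] per class, in canonical class order.  Task
#' `t` has the samples of class `t` as positives and everything else as
#' negatives, so the positive counts over all tasks sum to `n`.
#'
#' @inheritParams class_order
#' @return Named list of `binary_task` objects, one per class.
#' @export
binarize <- function(dataset, class_order = NULL) {
  classes <- class_order(dataset, class_order)
  tasks <- lapply(classes, function(cl) binary_task(dataset, cl))
  names(tasks) <- classes
  tasks
}
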