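#' Fit the direct classifier
#'
#' End-to-end training: optional outlier adjustment of the whole multi-class
#' training set, one-vs-rest decomposition, integrated gene ranking and
#' forward informative-gene selection per class.  The model keeps the
#' adjusted training data because prediction is transductive: each query
#' sample is merged into the training data and scored under candidate
#' labels, so there are no fitted coefficients at all.
#'
#' @param train An [expression_dataset()]; every class needs at least 2
#'   samples.
#' @param config An [rs_config()].
#' @return An object of class `dc_model`: list with `dataset` (adjusted
#'   training data), `classes` (tournament order), `bdig` (named list of
#'   informative gene subsets), `benchmarks`, `selections` (full traces),
#'   `outlier_report` and `config`.
#' @examples
#' \donttest{
#' d <- generate_dataset(synthetic_spec(classes = 2, per_class = 6,
#'                                      patterns = "I", noise_genes = 4,
#'                                      seed = 1))
#' model <- dc_fit(d)
#' dc_evaluate(model, d)$accuracy
#' }
#' @export
dc_fit <- function(train, config = rs_config()) {
  validate_dataset(train)
  counts <- table(train$labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 training samples; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  report <- NULL
  if (config$outlier_adjust) {
    adj <- adjust_outliers(train, config)
    train <- adj$dataset
    report <- adj$report
  }
  tasks <- binarize(train, config$class_order)
  selections <- lapply(tasks, function(task) {
    rk <- integrated_rank(task, config$backend, config$chi2_correction)
    forward_select(task, rk, config$B, config$backend,
                   config$chi2_correction)
  })
  structure(list(dataset = train,
                 classes = names(tasks),
                 bdig = lapply(selections, `[[`, "selected"),
                 benchmarks = vapply(selections, `[[`, numeric(1),
                                     "benchmark"),
                 selections = selections,
                 outlier_report = report,
                 config = config),
            class = "dc_model")
}

#' @export
print.dc_model <- function(x, ...) {
  cat(sprintf("dc_model: %d classes, %d training samples, backend '%s'\n",
              length(x$classes), nrow(x$dataset$values), x$config$backend))
  for (cl in x$classes)
    cat(sprintf("  %s: %d genes (LOOCV MCC %.3f): %s\n", cl,
                length(x$bdig[[cl]]), x$benchmarks[[cl]],
                paste(x$bdig[[cl]], collapse = ", ")))
  invisible(x)
}

## one paired-votes contest: current winner `a` vs challenger `b`; the
## training data is restricted to the two classes and the union of their
## informative genes, the query is merged under each label in turn, and the
## class with the strictly higher network score wins (tie -> challenger)
.contest <- function(model, sample, a, b) {
  genes <- union(model$bdig[[a]], model$bdig[[b]])
  keep <- model$dataset$labels %in% c(a, b)
  X <- model$dataset$values[keep, genes, drop = FALSE]
  pos <- model$dataset$labels[keep] == a
  sv <- sample[genes]
  if (anyNA(sv))
    stop("sample is missing values for: ",
         paste(genes[is.na(sv)], collapse = ", "))
  Xm <- rbind(X, matrix(sv, 1L, dimnames = list("query", genes)))
  cfg <- model$config
  s_a <- .subset_score(Xm, c(pos, TRUE), cfg$backend, cfg$chi2_correction)
  s_b <- .subset_score(Xm, c(pos, FALSE), cfg$backend, cfg$chi2_correction)
  list(winner = if (s_a > s_b) a else b, score_a = s_a, score_b = s_b)
}

## tournament over the model's class order: m - 1 contests, last winner is
## the prediction
.predict_one <- function(model, sample) {
  classes <- model$classes
  winner <- classes[1L]
  votes <- vector("list", length(classes) - 1L)
  for (k in seq_along(classes)[-1L]) {
    ct <- .contest(model, sample, winner, classes[k])
    votes[[k - 1L]] <- data.frame(class_a = winner, class_b = classes[k],
                                  score_a = ct$score_a, score_b = ct$score_b,
                                  winner = ct$winner,
                                  stringsAsFactors = FALSE)
    winner <- ct$winner
  }
  list(predicted = winner, votes = do.call(rbind, votes))
}

#' Predict class labels with a fitted direct classifier
#'
#' Paired-votes tournament in the model's class order: the first class meets
#' the second; the winner of each contest meets the next class; the last
#' winner (after `m - 1` contests) is the prediction.  Each contest is a
#' transductive binary comparison restricted to the two classes' training
#' samples and the union of their informative gene subsets.
#'
#' @param object A `dc_model` from [dc_fit()].
#' @param newdata An [expression_dataset()], or a numeric matrix / data
#'   frame of samples x genes covering every informative gene.
#' @param trace Logical: attach the per-sample vote sequences as attribute
#'   `"votes"`?
#' @param ... Unused.
#' @return Character vector of predicted class labels, one per sample.
#' @export
predict.dc_model <- function(object, newdata, trace = FALSE, ...) {
  X <- if (inherits(newdata, "expression_dataset")) newdata$values
       else as.matrix(newdata)
  needed <- unique(unlist(object$bdig, use.names = FALSE))
  if (!all(needed %in% colnames(X)))
    stop("test data lacks informative genes: ",
         paste(setdiff(needed, colnames(X)), collapse = ", "))
  out <- lapply(seq_len(nrow(X)), function(i) .predict_one(object, X[i, ]))
  pred <- vapply(out, `[[`, character(1), "predicted")
  names(pred) <- rownames(X)
  if (trace) attr(pred, "votes") <- lapply(out, `[[`, "votes")
  pred
}

#' Evaluate a direct classifier on a labeled test set
#'
#' Runs the paired-votes prediction on every test sample and reports the
#' accuracy (correctly classified / total).  Test samples are never
#' outlier-adjusted.  A test label the model has never seen is counted as an
#' error and triggers a warning.
#'
#' @param model A `dc_model`.
#' @param test An [expression_dataset()] whose genes cover every informative
#'   gene of the model.
#' @return List with `predictions` (data frame: sample, truth, predicted,
#'   correct) and `accuracy`.
#' @export
dc_evaluate <- function(model, test) {
  validate_dataset(test)
  unseen <- setdiff(unique(test$labels), model$classes)
  if (length(unseen))
    warning("test labels never seen in training (counted as errors): ",
            paste(unseen, collapse = ", "))
  pred <- predict(model, test)
  df <- data.frame(sample = rownames(test$values), truth = test$labels,
                   predicted = unname(pred),
                   correct = unname(pred) == test$labels,
                   stringsAsFactors = FALSE)
  list(predictions = df, accuracy = mean(df$correct))
}
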