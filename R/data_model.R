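#' Labeled expression dataset
#'
#' Bundles a numeric samples x genes expression matrix with one class label
#' per sample.  This is the universal input of every downstream step:
#' outlier adjustment, one-vs-rest binarization, gene ranking, informative
#' gene selection and classification.
#'
#' @param values Numeric matrix, `n` samples (rows) x `p` genes (columns).
#'   Expression units are arbitrary; no missing values are allowed.
#' @param labels Character (or factor) vector of length `n` giving the class
#'   of each sample.  At least two distinct classes are required.
#' @param sample_ids,gene_ids Optional identifier vectors; default to the
#'   dimnames of `values` or to `S1..Sn` / `G1..Gp`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (matrix with ids as dimnames) and `labels` (character vector).
#' @examples
#' d <- expression_dataset(matrix(rnorm(24), 4, 6),
#'                         labels = c("A", "A", "B", "B"))
#' dim(d$values)
#' @export
expression_dataset <- function(values, labels, sample_ids = NULL,
                               gene_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.character(labels)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(gene_ids))
  obj <- structure(list(values = values, labels = labels),
                   class = "expression_dataset")
  validate_dataset(obj)
}

#' Validate an expression dataset
#'
#' Checks the structural invariants: at least two samples, one gene and two
#' classes, every class non-empty, unique identifiers and a fully observed
#' numeric matrix.  Called by all constructors; exported because readers of
#' foreign files may want to re-validate after manual edits.
#'
#' @param x An `expression_dataset`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "expression_dataset"))
  v <- x$values
  n <- nrow(v); p <- ncol(v)
  if (n < 2L) stop("dataset must contain at least 2 samples, got ", n)
  if (p < 1L) stop("dataset must contain at least 1 gene")
  if (length(x$labels) != n)
    stop("labels length (", length(x$labels), ") != number of samples (", n, ")")
  if (anyNA(v) || any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)
    stop("non-finite expression values at (sample, gene): ",
         paste(sprintf("(%s, %s)", rownames(v)[bad[, 1L]],
                       colnames(v)[bad[, 2L]]), collapse = ", "))
  }
  if (anyNA(x$labels)) stop("missing class labels")
  if (length(unique(x$labels)) < 2L)
    stop("at least 2 distinct classes are required")
  if (anyDuplicated(rownames(v)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  x
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expression_dataset: %d samples x %d genes, %d classes\n",
              nrow(x$values), ncol(x$values), length(tab)))
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Class order of a dataset
#'
#' Canonical class order used for one-vs-rest decomposition and the
#' paired-votes tournament: first appearance in the sample labels, unless an
#' explicit override is given.
#'
#' @param dataset An `expression_dataset`.
#' @param class_order Optional character vector; must be a permutation of the
#'   observed classes.
#' @return Character vector of class identifiers.
#' @export
class_order <- function(dataset, class_order = NULL) {
  observed <- unique(dataset$labels)
  if (is.null(class_order)) return(observed)
  class_order <- as.character(class_order)
  if (!setequal(class_order, observed) ||
      length(class_order) != length(observed))
    stop("class_order must be a permutation of the observed classes: ",
         paste(observed, collapse = ", "))
  class_order
}

.sep_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

## shortest decimal text that scans back to the identical double
.format_full <- function(x) {
  out <- sprintf("%.15g", x)
  for (fmt in c("%.16g", "%.17g")) {
    bad <- as.numeric(out) != x
    if (!any(bad)) break
    out[bad] <- sprintf(fmt, x[bad])
  }
  out
}

#' Read a labeled expression matrix from delimited text
#'
#' Reads a CSV (comma) or TSV/TXT (tab) file with one header line.  The first
#' column always holds row identifiers.  With `orientation =
#' "samples-as-rows"` the rows are samples, the remaining columns genes, and
#' the class label sits in the column named `label_column`.  With
#' `orientation = "genes-as-rows"` the rows are genes, the columns samples,
#' and the labels sit in the row whose identifier equals `label_column`.
#'
#' @param path Path to a delimited text file; the separator is chosen from
#'   the extension (`.csv` comma, anything else tab).
#' @param orientation `"samples-as-rows"` (default) or `"genes-as-rows"`.
#' @param label_column Name of the label column (or label row), default
#'   `"class"`.
#' @return An [expression_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path,
                         orientation = c("samples-as-rows", "genes-as-rows"),
                         label_column = "class") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for_path(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop("file has fewer than 2 columns: ", path)
  row_ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  if (orientation == "samples-as-rows") {
    if (!label_column %in% colnames(body))
      stop("label column '", label_column, "' not found in ", path)
    labels <- body[[label_column]]
    body <- body[, setdiff(colnames(body), label_column), drop = FALSE]
    values <- .parse_numeric_matrix(body, row_ids, colnames(body))
    expression_dataset(values, labels,
                       sample_ids = row_ids, gene_ids = colnames(body))
  } else {
    hit <- which(row_ids == label_column)
    if (length(hit) != 1L)
      stop("label row '", label_column, "' not found (or duplicated) in ", path)
    labels <- unlist(body[hit, ], use.names = FALSE)
    gene_ids <- row_ids[-hit]
    body <- body[-hit, , drop = FALSE]
    values <- .parse_numeric_matrix(body, gene_ids, colnames(body))
    expression_dataset(t(values), labels,
                       sample_ids = colnames(body), gene_ids = gene_ids)
  }
}

.parse_numeric_matrix <- function(body, row_ids, col_ids) {
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = nrow(body),
           dimnames = list(row_ids, col_ids)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    raw <- as.matrix(body)
    stop("non-numeric expression values at (row, column): ",
         paste(sprintf("(%s, %s) = '%s'", row_ids[bad[, 1L]],
                       col_ids[bad[, 2L]], raw[bad]), collapse = ", "))
  }
  m
}

#' Write a labeled expression matrix to delimited text
#'
#' Inverse of [read_dataset()]: values are written with enough decimal digits
#' that re-reading reproduces the binary doubles exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param orientation Layout of the file, as in [read_dataset()].
#' @param label_column Name under which the class labels are stored.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          orientation = c("samples-as-rows", "genes-as-rows"),
                          label_column = "class") {
  orientation <- match.arg(orientation)
  validate_dataset(dataset)
  if (label_column %in% colnames(dataset$values))
    stop("label column name '", label_column, "' collides with a gene id")
  sep <- .sep_for_path(path)
  v <- dataset$values
  txt <- matrix(.format_full(v), nrow = nrow(v), dimnames = dimnames(v))
  if (orientation == "samples-as-rows") {
    df <- data.frame(sample = rownames(v), txt, dataset$labels,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("sample", colnames(v), label_column)
  } else {
    df <- data.frame(gene = c(colnames(v), label_column),
                     rbind(t(txt), dataset$labels),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", rownames(v))
  }
  ok <- tryCatch(
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}
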