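## Synthetic expression data with planted joint-effect gene pairs.
##
## Six pair templates cover the qualitatively distinct ways a gene pair can
## separate two classes: consistent reversal of expression (I) or of
## relative expression (II), consistent expression (III) or relative
## expression (IV), a heterogeneous per-sample background that hides the
## class signal from any per-gene threshold (V), and an interaction pattern
## only visible in the joint endpoint split (VI).  Patterns V and VI have
## two alternating sample-row variants within each class; the others are
## constant within class.

.pattern_templates <- list(
  I   = list(pos = rbind(c(50, 100)),               neg = rbind(c(100, 50))),
  II  = list(pos = rbind(c(5, 100)),                neg = rbind(c(10, 50))),
  III = list(pos = rbind(c(50, 50)),                neg = rbind(c(100, 100))),
  IV  = list(pos = rbind(c(5, 50)),                 neg = rbind(c(10, 100))),
  V   = list(pos = rbind(c(50, 100), c(5, 10)),     neg = rbind(c(100, 50), c(10, 5))),
  VI  = list(pos = rbind(c(50, 50), c(100, 100)),   neg = rbind(c(50, 100), c(100, 50)))
)

#' The 8-sample, 12-gene joint-effect pattern fixture
#'
#' The exact binary-class simulation dataset carrying one noise-free gene
#' pair of each of the six joint-effect patterns (genes G1/G2 = pattern I
#' through G11/G12 = pattern VI): four positive and four negative samples,
#' the positive rows alternating between two row templates (which only
#' differ in the pattern V and VI genes), likewise the negative rows.
#'
#' @return An [expression_dataset()] with n = 8, p = 12 and classes
#'   `"+"` / `"-"`.
#' @examples
#' pattern_fixture()$values[, "G1"]
#' @export
pattern_fixture <- function() {
  pos1 <- c(50, 100, 5, 100, 50, 50, 5, 50, 50, 100, 50, 50)
  pos2 <- c(50, 100, 5, 100, 50, 50, 5, 50, 5, 10, 100, 100)
  neg1 <- c(100, 50, 10, 50, 100, 100, 10, 100, 100, 50, 50, 100)
  neg2 <- c(100, 50, 10, 50, 100, 100, 10, 100, 10, 5, 100, 50)
  values <- rbind(pos1, pos2, pos1, pos2, neg1, neg2, neg1, neg2)
  expression_dataset(values,
                     labels = c(rep("+", 4L), rep("-", 4L)),
                     sample_ids = paste0("S", 1:8),
                     gene_ids = paste0("G", 1:12))
}

#' Specification of a synthetic pattern-planted dataset
#'
#' @param classes Number of classes `m >= 2`, or a character vector of class
#'   names.
#' @param per_class Samples per class (scalar or one count per class).
#' @param patterns Planted gene pairs: a character vector of pattern ids
#'   (`"I"`..`"VI"`, all targeting class 1), or a data frame with columns
#'   `pattern` and `target` (class name or index).  Each entry plants one
#'   gene pair (2 genes).
#' @param noise_genes Number of background noise genes, i.i.d. uniform on
#'   `noise_range` across all samples and classes.
#' @param jitter_sd Additive Gaussian jitter on the planted templates; the
#'   default `NULL` uses 5% of each pattern's template value range.
#' @param noise_range Range of the uniform noise genes (default `c(5, 110)`,
#'   spanning the template values).
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(classes = 2, per_class = 20,
                           patterns = c("I", "II", "III", "IV", "V", "VI"),
                           noise_genes = 0, jitter_sd = NULL,
                           noise_range = c(5, 110), seed = 1L) {
  class_names <- if (is.character(classes)) classes
                 else paste0("class", seq_len(classes))
  m <- length(class_names)
  if (m < 2L) stop("at least 2 classes are required")
  per_class <- rep_len(as.integer(per_class), m)
  if (any(per_class < 1L)) stop("every class needs at least one sample")
  if (is.character(patterns))
    patterns <- data.frame(pattern = patterns, target = class_names[1L],
                           stringsAsFactors = FALSE)
  if (is.list(patterns) && !is.data.frame(patterns))
    patterns <- as.data.frame(patterns, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern", "target") %in% names(patterns)))
  if (is.numeric(patterns$target))
    patterns$target <- class_names[patterns$target]
  if (!all(patterns$pattern %in% names(.pattern_templates)))
    stop("unknown pattern ids: ",
         paste(setdiff(patterns$pattern, names(.pattern_templates)),
               collapse = ", "))
  if (!all(patterns$target %in% class_names))
    stop("pattern targets must be class names")
  structure(list(class_names = class_names, per_class = per_class,
                 patterns = patterns, noise_genes = as.integer(noise_genes),
                 jitter_sd = jitter_sd, noise_range = noise_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic pattern-planted expression dataset
#'
#' Instantiates each planted pattern's two-gene template: samples of the
#' target class get the pattern's positive template rows (alternating where
#' the pattern has two row variants), all other samples the negative rows,
#' plus additive Gaussian jitter.  Noise genes are i.i.d. uniform.  The
#' result is fully determined by `spec$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_dataset()] with
#'   `2 * nrow(spec$patterns) + spec$noise_genes` genes.  Planted genes are
#'   named `<pattern><a|b>_<target>`, noise genes `noise<k>`.
#' @examples
#' d <- generate_dataset(synthetic_spec(per_class = 4, patterns = "I",
#'                                      noise_genes = 2, seed = 42))
#' d
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  labels <- rep(spec$class_names, spec$per_class)
  n <- length(labels)
  within_idx <- unlist(lapply(spec$per_class, seq_len), use.names = FALSE)
  cols <- list()
  ids <- character()
  for (k in seq_len(nrow(spec$patterns))) {
    pat <- spec$patterns$pattern[k]
    target <- spec$patterns$target[k]
    tmpl <- .pattern_templates[[pat]]
    sd_k <- if (is.null(spec$jitter_sd))
      0.05 * (max(tmpl$pos, tmpl$neg) - min(tmpl$pos, tmpl$neg))
      else spec$jitter_sd
    base <- matrix(0, n, 2L)
    for (i in seq_len(n)) {
      rows <- if (labels[i] == target) tmpl$pos else tmpl$neg
      base[i, ] <- rows[(within_idx[i] - 1L) %% nrow(rows) + 1L, ]
    }
    if (sd_k > 0) base <- base + matrix(stats::rnorm(2L * n, 0, sd_k), n, 2L)
    cols[[length(cols) + 1L]] <- base
    ids <- c(ids, paste0(pat, c("a", "b"), "_", target))
  }
  if (spec$noise_genes > 0L) {
    cols[[length(cols) + 1L]] <-
      matrix(stats::runif(n * spec$noise_genes, spec$noise_range[1L],
                          spec$noise_range[2L]),
             n, spec$noise_genes)
    ids <- c(ids, sprintf("noise%03d", seq_len(spec$noise_genes)))
  }
  ids <- make.unique(ids)  # the same pattern may target a class repeatedly
  expression_dataset(do.call(cbind, cols), labels,
                     sample_ids = paste0("S", seq_len(n)), gene_ids = ids)
}
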