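#' Pipeline configuration
#'
#' Collects every tunable of the ranking/selection/classification pipeline in
#' one place.  The defaults reproduce the method's reference settings:
#' outlier significance level `alpha = 0.05` with the two-sided normal
#' quantile `u_alpha = 1.96`, scan bound `B = 100`, relative-simplicity score
#' backend, and the continuity-corrected 2x2 chi-square without flooring.
#'
#' @param alpha Significance level of the per-gene outlier band (an
#'   expression value outside mean +/- `u_alpha` * sd is adjusted).
#' @param u_alpha Two-sided normal quantile paired with `alpha`.  Defaults to
#'   the conventional rounded 1.96 when `alpha` is 0.05, otherwise to
#'   `qnorm(1 - alpha / 2)`.
#' @param sd_estimator `"sample"` (n - 1 denominator, default) or
#'   `"population"`; used by the outlier adjustment only.
#' @param outlier_adjust Logical: run outlier adjustment inside [dc_fit()]?
#' @param B Upper bound on the number of top-ranked genes scanned by forward
#'   selection.
#' @param backend Score backend: `"rs"` (relative simplicity, default),
#'   `"entropy"` or `"chi2"`.  See [score_backend()].
#' @param chi2_correction Continuity-correction variant of the 2x2
#'   chi-square: `"yates_nofloor"` (default), `"yates"`, or `"none"`.
#' @param class_order Optional explicit class order for one-vs-rest tasks and
#'   the paired-votes tournament; default is first appearance in the data.
#' @return A list of class `rs_config`.
#' @export
rs_config <- function(alpha = 0.05, u_alpha = NULL,
                      sd_estimator = c("sample", "population"),
                      outlier_adjust = TRUE,
                      B = 100L,
                      backend = c("rs", "entropy", "chi2"),
                      chi2_correction = c("yates_nofloor", "yates", "none"),
                      class_order = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.null(u_alpha))
    u_alpha <- if (identical(alpha, 0.05)) 1.96 else
      stats::qnorm(1 - alpha / 2)
  stopifnot(is.numeric(u_alpha), u_alpha > 0, B >= 1)
  structure(list(alpha = alpha, u_alpha = u_alpha,
                 sd_estimator = match.arg(sd_estimator),
                 outlier_adjust = isTRUE(outlier_adjust),
                 B = as.integer(B),
                 backend = match.arg(backend),
                 chi2_correction = match.arg(chi2_correction),
                 class_order = class_order),
            class = "rs_config")
}

#' @export
print.rs_config <- function(x, ...) {
  cat("rs_config:\n")
  cat(sprintf("  alpha = %g (u = %g, %s sd), outlier_adjust = %s\n",
              x$alpha, x$u_alpha, x$sd_estimator, x$outlier_adjust))
  cat(sprintf("  backend = %s, chi2_correction = %s, B = %d\n",
              x$backend, x$chi2_correction, x$B))
  invisible(x)
}
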