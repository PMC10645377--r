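#' Construct a gene-by-sample expression matrix
#'
#' A plain numeric matrix (genes as rows) carrying its normalization state in
#' the `"scale"` attribute so every consumer can check it receives data on
#' the scale it expects. Gene identifiers are opaque strings; no symbol
#' remapping is performed.
#'
#' @param values numeric matrix with unique row (gene) and column (sample)
#'   names.
#' @param scale one of `"raw_counts"`, `"log2_cpm"`, `"log2_fpkm"`,
#'   `"quantile_normal"`.
#' @return the matrix with class `expr_matrix`.
#' @export
expression_matrix <- function(values,
                              scale = c("raw_counts", "log2_cpm",
                                        "log2_fpkm", "quantile_normal")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_("gene (row) and sample (column) names are required")
  if (anyDuplicated(rownames(values)))
    stop_("duplicated gene identifiers: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_("duplicated sample identifiers")
  if (scale == "raw_counts" && any(values < 0, na.rm = TRUE))
    stop_("raw counts must be nonnegative")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
#' @rdname expression_matrix
expr_scale <- function(x) attr(x, "scale") %||% NA_character_

#' TMM normalization to log2 counts per million
#'
#' Between-sample normalization by the trimmed mean of M-values (the
#' canonical 30% M / 5% A trims with precision weighting, as implemented in
#' edgeR, which is also the implementation used for the original analyses
#' this package reproduces). Scaling factors are renormalized to geometric
#' mean 1. Log2 CPM is then computed against the effective library size
#' (library size x factor) with a 0.5 pseudo-count:
#' \deqn{log2( (y + 0.5) / (N \cdot f) \cdot 10^6 )}
#'
#' @param counts an [expression_matrix()] on the `raw_counts` scale with at
#'   least two samples.
#' @return list with `factors` (named per-sample scaling factors) and
#'   `logcpm` (an `expr_matrix` on the `log2_cpm` scale).
#' @export
tmm_normalize <- function(counts) {
  if (!identical(expr_scale(counts), "raw_counts"))
    stop_("tmm_normalize requires raw counts (scale attribute 'raw_counts')")
  if (ncol(counts) < 2L) stop_("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_("sample(s) with zero total count: ",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  m <- unclass(counts); attr(m, "scale") <- NULL
  f <- edgeR::calcNormFactors(m, lib.size = lib, method = "TMM")
  names(f) <- colnames(counts)
  eff <- lib * f
  logcpm <- log2(sweep(m + 0.5, 2L, eff, "/") * 1e6)
  list(factors = f,
       logcpm = expression_matrix(logcpm, "log2_cpm"))
}

#' Ordered quantile (rank-based inverse normal) normalization
#'
#' Maps values to normal quantiles by their ranks, \eqn{\Phi^{-1}((r - 0.5)/n)}
#' with average ranks for ties, so that any strictly monotone transform of
#' the input yields an identical output.
#'
#' @param values numeric vector with at least 3 finite values.
#' @return vector of normal scores in the same order as the input.
#' @export
ordered_quantile_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 3L)
    stop_("need at least 3 values")
  if (any(!is.finite(values))) stop_("values must be finite")
  if (diff(range(values)) == 0)
    stop_("all values identical: no ordering information")
  n <- length(values)
  out <- stats::qnorm((rank(values, ties.method = "average") - 0.5) / n)
  names(out) <- names(values)
  out
}

#' Call SLFN11 expressor status across a cohort
#'
#' SLFN11 transcript levels in prostate tumors are typically bimodal: an
#' unexpressed (often epigenetically silenced) mode and an expressing mode.
#' The default `mixture` method fits one- and two-component Gaussian
#' mixtures (mclust, BIC-selected) to the supplied values; samples are
#' called positive when their posterior probability for the higher-mean
#' component exceeds 0.5. The fit is on the values as given: a rank-based
#' inverse-normal transform would map any sample onto exact standard-normal
#' scores and erase the bimodality the mixture looks for, so
#' `quantile_normalize` is off by default and only useful to tame heavy
#' tails ahead of a threshold rule. If the
#' data do not support two components (one-component model preferred, or a
#' component weight below 0.02), the fit is treated as degenerate: with a
#' `threshold` supplied the threshold rule is applied with a warning,
#' otherwise every sample is called negative with a warning. The `threshold`
#' method simply compares raw values to a user cutoff. This mixture rule is
#' this package's default, pluggable operationalization of "expressor
#' status"; the method and its parameters are recorded in the result.
#'
#' @param expression named numeric vector of SLFN11 expression across the
#'   cohort (any monotone-equivalent scale for the mixture method).
#' @param method `"mixture"` (default, cohort size >= 20) or `"threshold"`.
#' @param threshold raw-scale cutoff; required for `method = "threshold"`,
#'   optional degenerate-fit fallback for `"mixture"`.
#' @param quantile_normalize apply ordered quantile normalization before the
#'   mixture fit (default FALSE; see Details).
#' @return list of class `slfn11_call`: `status` (named logical),
#'   `positive_fraction`, `method`, `degenerate`, `parameters`.
#' @export
call_slfn11 <- function(expression, method = c("mixture", "threshold"),
                        threshold = NULL, quantile_normalize = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(expression)) stop_("expression must be numeric")

  finish <- function(status, method, degenerate, parameters) {
    names(status) <- names(expression)
    structure(list(status = status, positive_fraction = mean(status),
                   method = method, degenerate = degenerate,
                   parameters = parameters),
              class = "slfn11_call")
  }

  if (method == "threshold") {
    if (is.null(threshold)) stop_("threshold method requires a cutoff")
    return(finish(expression > threshold, "threshold", FALSE,
                  list(threshold = threshold)))
  }

  if (length(expression) < 20L)
    stop_("mixture method needs a cohort of at least 20 samples")
  x <- if (quantile_normalize) ordered_quantile_normalize(expression)
       else expression
  fit <- mclust::Mclust(x, G = 1:2, modelNames = c("E", "V"),
                        verbose = FALSE)
  # (mclust::Mclust evaluates mclustBIC in the caller; see package imports)
  degenerate <- is.null(fit) || fit$G < 2L || min(fit$parameters$pro) < 0.02
  if (degenerate) {
    if (!is.null(threshold)) {
      warn_("degenerate mixture fit; falling back to threshold rule")
      return(finish(expression > threshold, "threshold_fallback", TRUE,
                    list(threshold = threshold)))
    }
    warn_("degenerate mixture fit and no threshold supplied; ",
          "calling all samples negative")
    return(finish(rep(FALSE, length(expression)), "mixture", TRUE,
                  list(G = if (is.null(fit)) NA_integer_ else fit$G)))
  }
  hi <- which.max(fit$parameters$mean)
  status <- fit$z[, hi] > 0.5
  finish(status, "mixture", FALSE,
         list(G = fit$G, model = fit$modelName,
              means = fit$parameters$mean,
              sds = sqrt(fit$parameters$variance$sigmasq),
              weights = fit$parameters$pro))
}

#' @export
print.slfn11_call <- function(x, ...) {
  cat(sprintf("<slfn11_call> %s%s: %d/%d positive (%.1f%%)\n",
              x$method, if (x$degenerate) " [degenerate]" else "",
              sum(x$status), length(x$status), 100 * x$positive_fraction))
  invisible(x)
}
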