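#' Construct a gene set
#'
#' @param name gene-set name.
#' @param genes character vector of member gene identifiers; duplicates are
#'   removed with a warning.
#' @param description free-text description.
#' @return list of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warn_("gene set '", name, "' has duplicated members; de-duplicating")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' Single-sample gene-set enrichment (ssGSEA-style) scores
#'
#' For each sample, genes are ranked by expression (average ranks for ties)
#' and walked in decreasing order; the enrichment score is the sum over the
#' ranked list of the difference between the in-set empirical CDF weighted by
#' \eqn{|rank|^\alpha} and the unweighted out-of-set CDF. Because only ranks
#' enter, scores are invariant to any strictly increasing per-sample
#' transform of expression. With `normalize = TRUE` (the default, matching
#' the cited method's behavior) all raw scores are divided by the global
#' score range (max - min over the whole score matrix), making scores
#' comparable across signatures.
#'
#' @param matrix an expression matrix (genes x samples) on a
#'   per-sample-comparable scale.
#' @param gene_sets a single [gene_set()] or a list of them.
#' @param alpha rank-weight exponent (default 0.25, the canonical ssGSEA
#'   default).
#' @param normalize rescale scores by the global range (default TRUE).
#' @return for a single gene set, a named per-sample score vector; for a
#'   list, a `signature_scores` object (see [z_transform()]).
#' @export
ssgsea_score <- function(matrix, gene_sets, alpha = 0.25, normalize = TRUE) {
  single <- inherits(gene_sets, "gene_set")
  sets <- if (single) list(gene_sets) else gene_sets
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "gene_set")))
  m <- as.matrix(matrix)
  n_genes <- nrow(m)
  genes <- rownames(m)
  if (is.null(genes)) stop_("matrix must have gene row names")

  memberships <- lapply(sets, function(s) {
    inset <- genes %in% s$genes
    k <- sum(inset)
    if (k < 2L)
      stop_("gene set '", s$name, "' has fewer than 2 genes in the matrix")
    if (k == n_genes)
      stop_("gene set '", s$name, "' covers every gene (no complement)")
    inset
  })

  score_one <- function(expr) {
    r <- rank(expr, ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    w <- abs(r[ord])^alpha
    vapply(memberships, function(inset) {
      io <- inset[ord]
      win <- w * io
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!io) / (n_genes - sum(io))
      sum(p_in - p_out)
    }, numeric(1))
  }

  raw <- vapply(seq_len(ncol(m)), function(j) score_one(m[, j]),
                numeric(length(sets)))
  raw <- matrix(raw, nrow = length(sets),
                dimnames = list(vapply(sets, `[[`, "", "name"), colnames(m)))
  if (normalize) {
    rng <- diff(range(raw))
    if (rng == 0) warn_("all scores identical; skipping range rescaling")
    else raw <- raw / rng
  }
  if (single) return(raw[1L, ])
  structure(list(raw = raw, z = NULL, alpha = alpha, normalized = normalize),
            class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> %d signatures x %d samples (alpha=%g%s%s)\n",
              nrow(x$raw), ncol(x$raw), x$alpha,
              if (x$normalized) ", range-normalized" else "",
              if (is.null(x$z)) "" else ", z-scaled"))
  invisible(x)
}

#' Z-scale signature scores across the cohort
#'
#' Per signature, \eqn{(x - mean) / sd} across samples, with the sample
#' (n - 1) standard deviation. Rank order within each signature is preserved.
#'
#' @param scores a `signature_scores` object with at least 2 samples.
#' @return the object with its `z` matrix filled.
#' @export
z_transform <- function(scores) {
  stopifnot(inherits(scores, "signature_scores"))
  if (ncol(scores$raw) < 2L) stop_("need at least 2 samples")
  sds <- apply(scores$raw, 1L, stats::sd)
  if (any(sds == 0))
    stop_("zero variance in signature(s): ",
          paste(rownames(scores$raw)[sds == 0], collapse = ", "))
  scores$z <- (scores$raw - rowMeans(scores$raw)) / sds
  scores
}

#' Call tumor phenotype from AR and NE signature scores
#'
#' Quadrant rule on z-scaled androgen-receptor (AR) and neuroendocrine (NE)
#' pathway scores: AR+/NE- adenocarcinoma (`ARPC`), AR-/NE- double-negative
#' (`DNPC`), AR-/NE+ small-cell neuroendocrine (`SCNPC`), and AR+/NE+
#' (`amphicrine`). A score is "positive" when strictly above its threshold
#' (default 0 on the z scale).
#'
#' @param ar_score,ne_score numeric z-scores on the same cohort.
#' @param ar_threshold,ne_threshold cutoffs (default 0).
#' @return character vector in
#'   `c("ARPC", "DNPC", "SCNPC", "amphicrine")`.
#' @export
call_phenotype <- function(ar_score, ne_score,
                           ar_threshold = 0, ne_threshold = 0) {
  stopifnot(length(ar_score) == length(ne_score))
  ar <- ar_score > ar_threshold
  ne <- ne_score > ne_threshold
  out <- ifelse(ar & !ne, "ARPC",
         ifelse(!ar & !ne, "DNPC",
         ifelse(!ar & ne, "SCNPC", "amphicrine")))
  names(out) <- names(ar_score)
  out
}

#' Univariate correlation screen of signature scores against nAUC
#'
#' Correlates each signature's z-score with the per-model median nAUC
#' (Spearman by default), with two-sided p-values and Benjamini-Hochberg
#' adjustment across all tested signatures. Signatures with a constant score
#' vector are reported with an undefined coefficient and excluded from the
#' FDR ranking. Rows are sorted by absolute coefficient, significant
#' signatures (FDR <= `fdr_threshold`) first.
#'
#' @param nauc named numeric vector of median nAUC per model.
#' @param scores a `signature_scores` object (z-scaled automatically when
#'   needed) or a signatures-by-samples numeric matrix.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param fdr_threshold significance cutoff on the adjusted p (default 0.05).
#' @return data.frame with columns `signature`, `coefficient`, `p_value`,
#'   `fdr`, `significant`.
#' @export
correlate_with_response <- function(nauc, scores,
                                    method = c("spearman", "pearson"),
                                    fdr_threshold = 0.05) {
  method <- match.arg(method)
  z <- if (inherits(scores, "signature_scores")) {
    if (is.null(scores$z)) scores <- z_transform(scores)
    scores$z
  } else as.matrix(scores)
  shared <- intersect(names(nauc), colnames(z))
  if (length(shared) < 4L) stop_("need at least 4 shared models")
  z <- z[, shared, drop = FALSE]
  y <- nauc[shared]

  res <- t(vapply(seq_len(nrow(z)), function(i) {
    x <- z[i, ]
    if (stats::sd(x) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = method, exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  out <- data.frame(signature = rownames(z), coefficient = res[, 1],
                    p_value = res[, 2], fdr = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr <= fdr_threshold
  out <- out[order(!out$significant, -abs(out$coefficient),
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise rank-sum comparisons between groups
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups, with Holm
#' adjustment across the pairs. Groups with fewer than 2 values are excluded
#' with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return data.frame with `group1`, `group2`, `p_value`, `p_adjusted`.
#' @export
group_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  split_vals <- split(values, groups)
  small <- vapply(split_vals, length, 0L) < 2L
  if (any(small)) {
    warn_("excluding group(s) with fewer than 2 values: ",
          paste(names(split_vals)[small], collapse = ", "))
    split_vals <- split_vals[!small]
  }
  if (length(split_vals) < 2L) stop_("need at least 2 groups of size >= 2")
  pairs <- utils::combn(names(split_vals), 2L)
  p <- apply(pairs, 2L, function(pr) {
    suppressWarnings(
      stats::wilcox.test(split_vals[[pr[1]]], split_vals[[pr[2]]],
                         alternative = "two.sided"))$p.value
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p_value = p,
             p_adjusted = stats::p.adjust(p, method = "holm"),
             stringsAsFactors = FALSE)
}
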