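# Independent oracles used across the suite. Each is a direct, unoptimized
# transcription of the method's definition, kept deliberately separate from
# the package implementation it checks.

# ssGSEA running sum by explicit gene-by-gene walk
ssgsea_oracle <- function(expr, set_genes, alpha = 0.25) {
  r <- rank(expr, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  inset <- names(expr)[ord] %in% set_genes
  w <- r[ord]^alpha
  N <- length(expr); k <- sum(inset)
  win_total <- sum(w[inset])
  es <- 0; cin <- 0; cout <- 0
  for (i in seq_len(N)) {
    if (inset[i]) cin <- cin + w[i] else cout <- cout + 1
    es <- es + cin / win_total - cout / (N - k)
  }
  es
}

# trimmed weighted mean of M-values, written from the method definition:
# reference = sample whose 0.75 quantile of count/library is closest to the
# mean; zero counts excluded pairwise; 30% two-sided trim on M, 5% on A;
# inverse-asymptotic-variance weights; factors scaled to geometric mean 1
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fs <- vapply(seq_len(ncol(counts)), function(j) {
    y1 <- counts[, j]; y2 <- counts[, ref]
    n1 <- lib[j]; n2 <- lib[ref]
    keep0 <- y1 > 0 & y2 > 0
    y1 <- y1[keep0]; y2 <- y2[keep0]
    M <- log2((y1 / n1) / (y2 / n2))
    A <- 0.5 * log2((y1 / n1) * (y2 / n2))
    w <- (n1 - y1) / (n1 * y1) + (n2 - y2) / (n2 * y2)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  fs / exp(mean(log(fs)))
}

# fine-grid trapezoid of the exact 4PL curve, for AUC cross-checks
auc_fine_oracle <- function(top, bottom, ic50, slope, dmin, dmax,
                            n = 200001) {
  x <- seq(log10(dmin), log10(dmax), length.out = n)
  v <- bottom + (top - bottom) / (1 + (10^x / ic50)^slope)
  sum((v[-1] + v[-n]) / 2 * diff(x)) / (100 * (max(x) - min(x)))
}

make_counts <- function(m, genes = paste0("g", seq_len(nrow(m))),
                        samples = paste0("s", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, "raw_counts")
}
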