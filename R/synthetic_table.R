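#' Synthetic 26-model annotation table
#'
#' A synthetic reconstruction of a metastatic prostate cancer model panel
#' (26 models: 19 adenocarcinoma ARPC, 5 small-cell neuroendocrine SCNPC,
#' 2 double-negative DNPC) annotated with B7H3 level, genotype states,
#' SLFN11 expressor status, replication-stress and RB1 signature z-scores,
#' median nAUC and observed ADC response class. The rows are constructed --
#' not measured -- to jointly satisfy the published panel tallies: all
#' non-ARPC models are RB1-null/TP53-altered responders with nAUC in
#' 0.2-0.5; 8 of 8 SLFN11+ ARPC models respond; 3 of 11 SLFN11- ARPC models
#' respond (carried by CHD1 loss and ATR loss); 8 ARPC models do not
#' respond, 7 of the 8 SLFN11- nonresponders being TP53 wild-type (one of
#' them BRCA2-deficient); and 6 of 9 RB1-deficient models are SLFN11+.
#'
#' @return data.frame with one row per model.
#' @export
synthetic_model_table <- function() {
  row <- function(id, phen, b7h3, rb1, tp53, atr, chd1, brca2, slfn11,
                  rsz, rbz, nauc, resp) {
    data.frame(model_id = id, phenotype = phen, b7h3_level = b7h3,
               b7h3_positive = TRUE, RB1 = rb1, TP53 = tp53, ATR = atr,
               CHD1 = chd1, BRCA2 = brca2, slfn11 = slfn11,
               repstress_z = rsz, rb1_score_z = rbz, nauc_median = nauc,
               observed_response = resp, stringsAsFactors = FALSE)
  }
  bl <- "biallelic_loss"; alt <- "altered"; mwt <- "monoallelic_or_wt"
  out <- rbind(
    # non-ARPC: RB1-null, TP53-altered, uniformly responsive (nAUC 0.2-0.5)
    row("N01", "SCNPC", 5.7, bl, alt, "wt", "wt", "wt", TRUE,  2.1,  1.9, 0.22, "R"),
    row("N02", "SCNPC", 5.5, bl, alt, "wt", "wt", "wt", TRUE,  1.9,  1.7, 0.25, "R"),
    row("N03", "SCNPC", 5.9, bl, alt, "wt", "wt", "wt", TRUE,  1.7,  1.6, 0.30, "R"),
    row("N04", "SCNPC", 5.4, bl, alt, "wt", "wt", "wt", FALSE, 1.6,  1.5, 0.35, "R"),
    row("N05", "SCNPC", 5.6, bl, alt, "wt", "wt", "wt", FALSE, 1.4,  1.3, 0.40, "R"),
    row("N06", "DNPC",  5.8, bl, alt, "wt", "wt", "wt", TRUE,  1.8,  1.6, 0.28, "R"),
    row("N07", "DNPC",  5.3, bl, alt, "wt", "wt", "wt", FALSE, 1.3,  1.2, 0.45, "R"),
    # ARPC, RB1-deficient responders (SLFN11+)
    row("A01", "ARPC",  5.6, bl, alt, "wt", "wt", "wt", TRUE,  1.6,  1.4, 0.35, "R"),
    row("A02", "ARPC",  5.5, bl, alt, "wt", "wt", "wt", TRUE,  1.5,  1.3, 0.40, "R"),
    # ARPC, RB1-intact SLFN11+ responders (two with elevated RepStress)
    row("A03", "ARPC",  7.8, "wt", alt, "wt", "wt", "wt", TRUE,  1.3, 0.4, 0.35, "R"),
    row("A04", "ARPC",  7.5, "wt", alt, "wt", "wt", "wt", TRUE,  1.2, 0.3, 0.40, "R"),
    row("A05", "ARPC",  7.2, "wt", alt, "wt", "wt", "wt", TRUE,  0.5, 0.1, 0.45, "R"),
    row("A06", "ARPC",  7.0, "wt", alt, "wt", "wt", "wt", TRUE,  0.3, 0.0, 0.50, "R"),
    row("A07", "ARPC",  5.7, mwt,  alt, "wt", "wt", "wt", TRUE,  0.2, -0.1, 0.55, "R"),
    row("A08", "ARPC",  5.6, "wt", "wt", "wt", "wt", "wt", TRUE,  0.1, -0.2, 0.60, "R"),
    # ARPC, RB1-intact SLFN11- responders: crosslink-repair deficient
    row("A09", "ARPC",  5.8, "wt", alt,  "wt", alt,  "wt", FALSE, 0.0, -0.3, 0.45, "R"),
    row("A10", "ARPC",  5.9, "wt", "wt", "wt", alt,  "wt", FALSE, -0.1, -0.4, 0.50, "R"),
    row("A11", "ARPC",  5.5, "wt", "wt", alt,  "wt", "wt", FALSE, -0.2, -0.5, 0.55, "R"),
    # ARPC nonresponders (SLFN11-; 7 of 8 TP53 wild-type, one BRCA2-deficient)
    row("A12", "ARPC",  5.7, "wt", "wt", "wt", "wt", "wt",  FALSE, -0.5, -0.7, 0.85, "NR"),
    row("A13", "ARPC",  5.6, "wt", "wt", "wt", "wt", alt,   FALSE, -0.6, -0.8, 0.90, "NR"),
    row("A14", "ARPC",  5.8, "wt", mwt,  "wt", "wt", "wt",  FALSE, -0.7, -0.9, 0.95, "NR"),
    row("A15", "ARPC",  5.5, mwt,  "wt", "wt", "wt", "wt",  FALSE, -0.8, -1.0, 1.00, "NR"),
    row("A16", "ARPC",  5.4, "wt", "wt", "wt", "wt", "wt",  FALSE, -0.9, -1.1, 0.90, "NR"),
    row("A17", "ARPC",  5.6, "wt", mwt,  "wt", "wt", "wt",  FALSE, -1.0, -1.2, 0.95, "NR"),
    row("A18", "ARPC",  5.9, "wt", "wt", "wt", "wt", "wt",  FALSE, -1.1, -1.3, 0.85, "NR"),
    row("A19", "ARPC",  5.5, "wt", alt,  "wt", "wt", "wt",  FALSE, -0.4, -0.6, 0.80, "NR"))
  rownames(out) <- NULL
  out
}

#' Hill parameters reproducing an annotation table's nAUC values
#'
#' Maps each model's target median nAUC to four-parameter-logistic
#' parameters on a given dose grid such that the noise-free computed nAUC
#' (control flat at 100%) approximates the target: a steep curve (slope 3)
#' from 100% to 0% whose log10 IC50 sits the target fraction of the way
#' through the log10 dose span. Used to build dose-response fixtures whose
#' downstream summaries land in the annotated response-class ranges.
#'
#' @param table an annotation table with `model_id` and `nauc_median`.
#' @param dose_grid the dose grid the curves will be sampled on.
#' @return named list of `c(top, bottom, ic50, slope)` per model.
#' @export
synthetic_hill_params <- function(table,
                                  dose_grid = 4 * 10^seq(-6, 0, by = 1)) {
  l0 <- log10(min(dose_grid)); l1 <- log10(max(dose_grid))
  params <- lapply(seq_len(nrow(table)), function(i) {
    a <- table$nauc_median[i]
    c(top = 100, bottom = 0, ic50 = 10^(l0 + a * (l1 - l0)), slope = 3)
  })
  names(params) <- table$model_id
  params
}
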