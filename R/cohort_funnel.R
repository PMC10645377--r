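#' Merge polyA and capture cohort tables into unique samples
#'
#' Clinical transcriptome cohorts are often sequenced by two assays (polyA
#' and hybrid capture) that overlap in samples. The two tables are merged to
#' one record per unique `sample_id`; where both assays cover a sample, the
#' polyA record is kept (configurable priority). Conflicting tumor-content
#' values (differing by more than 0.05) trigger a warning, with the
#' priority value kept.
#'
#' @param polya,capture data.frames with at least a `sample_id` column.
#' @param priority which table wins for duplicated samples
#'   (default `"polya"`).
#' @return merged data.frame with an `assay` column.
#' @export
merge_unique <- function(polya, capture, priority = c("polya", "capture")) {
  priority <- match.arg(priority)
  stopifnot("sample_id" %in% names(polya), "sample_id" %in% names(capture))
  polya$assay <- "polya"; capture$assay <- "capture"
  first <- if (priority == "polya") polya else capture
  second <- if (priority == "polya") capture else polya
  dup <- intersect(first$sample_id, second$sample_id)
  if (length(dup) && !is.null(first$tumor_content) &&
      !is.null(second$tumor_content)) {
    tc1 <- first$tumor_content[match(dup, first$sample_id)]
    tc2 <- second$tumor_content[match(dup, second$sample_id)]
    bad <- which(abs(tc1 - tc2) > 0.05)
    if (length(bad))
      warn_("tumor_content differs by > 0.05 for sample(s) ",
            paste(dup[bad], collapse = ", "),
            "; keeping the ", priority, " value")
  }
  out <- rbind(first, second[!second$sample_id %in% first$sample_id, ,
                             drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Filter a cohort by tumor content
#'
#' Keeps samples whose tumor content is at least `min_fraction` (inclusive).
#' Samples with missing tumor content are dropped with a warning and counted
#' in the `dropped_missing` attribute.
#'
#' @param cohort data.frame with a `tumor_content` column (fractions in
#'   [0, 1]).
#' @param min_fraction inclusive minimum (default 0.30).
#' @return the filtered data.frame.
#' @export
filter_tumor_content <- function(cohort, min_fraction = 0.30) {
  stopifnot("tumor_content" %in% names(cohort))
  miss <- is.na(cohort$tumor_content)
  if (any(miss))
    warn_(sum(miss), " sample(s) dropped for missing tumor_content")
  kept <- cohort[!miss & cohort$tumor_content >= min_fraction, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "dropped_missing") <- sum(miss)
  kept
}

#' Sequential biomarker stratification funnel
#'
#' Partitions a (tumor-content-filtered) cohort through the ordered
#' biomarker stages used for clinical stratification:
#' \enumerate{
#'   \item RB1 homozygous alteration vs intact;
#'   \item among RB1-intact samples, SLFN11 expressor status (via the
#'     supplied caller on `SLFN11_expr`);
#'   \item among RB1-intact/SLFN11-negative samples, ATR or CHD1 loss;
#'   \item among the remainder, TP53 wild-type vs altered.
#' }
#' Samples selected at stages 1-3 are eligible (any single positive
#' biomarker); the eligible fraction is reported over the input cohort. At
#' every stage the two branches sum exactly to the stage input.
#'
#' @param cohort data.frame with columns `RB1_state`, `TP53_state`,
#'   `ATR_state`, `CHD1_state` (see [genotype_states]) and `SLFN11_expr`
#'   (numeric).
#' @param slfn11_caller function mapping a numeric expression vector to a
#'   logical status vector; defaults to the mixture rule of [call_slfn11()].
#' @return list of class `funnel_report` with a `stages` data.frame
#'   (`stage`, `n_in`, `n_selected`, `n_remaining`, `fraction_selected`),
#'   `eligible_n`, `eligible_fraction`, `total`.
#' @export
run_funnel <- function(cohort, slfn11_caller = NULL) {
  if (is.null(slfn11_caller))
    slfn11_caller <- function(x) call_slfn11(x, method = "mixture")$status
  need <- c("RB1_state", "TP53_state", "ATR_state", "CHD1_state",
            "SLFN11_expr")
  if (!all(need %in% names(cohort)))
    stop_("cohort must have columns: ", paste(need, collapse = ", "))
  n <- nrow(cohort)

  stage <- function(name, n_in, sel) {
    data.frame(stage = name, n_in = n_in, n_selected = sum(sel),
               n_remaining = n_in - sum(sel),
               fraction_selected = if (n_in > 0) sum(sel) / n_in else 0,
               stringsAsFactors = FALSE)
  }

  rb1_alt <- cohort$RB1_state == "biallelic_loss"
  s1 <- stage("RB1_homozygous_alteration", n, rb1_alt)

  intact <- cohort[!rb1_alt, , drop = FALSE]
  slfn_pos <- if (nrow(intact) > 0)
    as.logical(slfn11_caller(intact$SLFN11_expr)) else logical(0)
  s2 <- stage("SLFN11_expressed_RB1_intact", nrow(intact), slfn_pos)

  rem1 <- intact[!slfn_pos, , drop = FALSE]
  repair <- genotype_is_lof(rem1$ATR_state) | genotype_is_lof(rem1$CHD1_state)
  s3 <- stage("ATR_or_CHD1_loss", nrow(rem1), repair)

  rem2 <- rem1[!repair, , drop = FALSE]
  tp53_wt <- genotype_is_wt_like(rem2$TP53_state)
  s4 <- stage("TP53_wild_type_remainder", nrow(rem2), tp53_wt)

  eligible <- s1$n_selected + s2$n_selected + s3$n_selected
  structure(list(stages = rbind(s1, s2, s3, s4),
                 eligible_n = eligible,
                 eligible_fraction = if (n > 0) eligible / n else 0,
                 total = n),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("<funnel_report> %d samples\n", x$total))
  for (i in seq_len(nrow(x$stages))) {
    s <- x$stages[i, ]
    cat(sprintf("  %-28s %4d in -> %4d selected / %4d remaining (%.1f%%)\n",
                s$stage, s$n_in, s$n_selected, s$n_remaining,
                100 * s$fraction_selected))
  }
  cat(sprintf("  eligible (any positive biomarker): %d / %d (%.1f%%)\n",
              x$eligible_n, x$total, 100 * x$eligible_fraction))
  invisible(x)
}
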