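#' IHC H-score for one core
#'
#' Composite staining score for a tissue core scored by the percentage of
#' cells at each staining intensity (0 none, 1 weak, 2 moderate, 3 strong):
#' \deqn{H = \sum_{i=1}^{3} pct_i \times i} giving a range of 0-300.
#'
#' @param pct numeric vector of length 4: percentages of cells at intensities
#'   0, 1, 2, 3. Must be nonnegative and sum to 100 (within +/- 0.5 to absorb
#'   rounded tables).
#' @return H-score in [0, 300].
#' @export
compute_hscore <- function(pct) {
  pct <- as.numeric(pct)
  if (length(pct) != 4L) stop_("pct must have 4 entries (intensities 0-3)")
  if (any(!is.finite(pct)) || any(pct < 0))
    stop_("percentages must be finite and nonnegative")
  if (abs(sum(pct) - 100) > 0.5)
    stop_("percentages sum to ", sum(pct), ", expected 100 (+/- 0.5)")
  sum(pct * 0:3)
}

#' Per-core H-scores for a core table
#'
#' @param cores data.frame with columns `tumor_id`, `core_id`, `pct0`..`pct3`
#'   and optionally `evaluable` (logical; missing means all evaluable).
#'   Non-evaluable cores get an `NA` H-score.
#' @return the input with an `h_score` column appended.
#' @export
hscore_cores <- function(cores) {
  need <- c("tumor_id", "core_id", paste0("pct", 0:3))
  if (!all(need %in% names(cores)))
    stop_("core table must have columns: ", paste(need, collapse = ", "))
  if (is.null(cores$evaluable)) cores$evaluable <- TRUE
  pm <- as.matrix(cores[, paste0("pct", 0:3)])
  cores$h_score <- vapply(seq_len(nrow(cores)), function(i) {
    if (!isTRUE(cores$evaluable[i])) return(NA_real_)
    compute_hscore(pm[i, ])
  }, numeric(1))
  cores
}

#' Average triplicate core H-scores per tumor
#'
#' Arithmetic mean of per-core H-scores over evaluable cores only. A tumor
#' with no evaluable core is flagged `analyzed = FALSE` (not an error) and is
#' excluded from downstream counts.
#'
#' @param cores a core table as accepted by [hscore_cores()].
#' @return data.frame with one row per tumor: `tumor_id`, `h_score`,
#'   `n_cores` (evaluable), `analyzed`.
#' @export
average_cores <- function(cores) {
  scored <- hscore_cores(cores)
  by_tumor <- split(scored, scored$tumor_id)
  out <- do.call(rbind, lapply(by_tumor, function(d) {
    h <- d$h_score[!is.na(d$h_score)]
    data.frame(tumor_id = d$tumor_id[1],
               h_score = if (length(h)) mean(h) else NA_real_,
               n_cores = length(h), analyzed = length(h) > 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify B7H3 expressor status from an averaged H-score
#'
#' Positive iff the H-score is strictly greater than the cutoff (default 20).
#'
#' @param h averaged H-score(s) in [0, 300]; `NA` propagates.
#' @param cutoff positivity cutoff (default 20, strict `>`).
#' @return logical vector.
#' @export
classify_expressor <- function(h, cutoff = 20) {
  if (any(h < 0 | h > 300, na.rm = TRUE))
    stop_("H-scores must lie in [0, 300]")
  h > cutoff
}

#' Summarize a tissue microarray
#'
#' Counts evaluable tumors, expressors and non-expressors at the H-score
#' cutoff, and tabulates expressor status by phenotype when annotation is
#' available. Expressors and non-expressors always partition the evaluable
#' tumors.
#'
#' @param tumors data.frame as returned by [average_cores()], optionally with
#'   a `phenotype` column.
#' @param cutoff H-score positivity cutoff (default 20).
#' @return list of class `tma_summary` with `total`, `not_analyzed`,
#'   `evaluable`, `expressors`, `non_expressors`, `cutoff`, `by_phenotype`.
#' @export
summarize_tma <- function(tumors, cutoff = 20) {
  stopifnot(all(c("tumor_id", "h_score", "analyzed") %in% names(tumors)))
  ev <- tumors[tumors$analyzed, , drop = FALSE]
  pos <- classify_expressor(ev$h_score, cutoff)
  by_phen <- NULL
  if (!is.null(tumors$phenotype)) {
    by_phen <- table(phenotype = ev$phenotype,
                     expressor = factor(pos, levels = c(FALSE, TRUE),
                                        labels = c("negative", "positive")))
  }
  structure(list(total = nrow(tumors),
                 not_analyzed = sum(!tumors$analyzed),
                 evaluable = nrow(ev),
                 expressors = sum(pos),
                 non_expressors = sum(!pos),
                 cutoff = cutoff,
                 by_phenotype = by_phen),
            class = "tma_summary")
}

#' @export
print.tma_summary <- function(x, ...) {
  cat(sprintf(
    "<tma_summary> %d tumors (%d not analyzed); of %d evaluable, %d expressors (H > %g) and %d non-expressors\n",
    x$total, x$not_analyzed, x$evaluable, x$expressors, x$cutoff,
    x$non_expressors))
  if (!is.null(x$by_phenotype)) print(x$by_phenotype)
  invisible(x)
}
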