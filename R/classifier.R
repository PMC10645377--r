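#' @name genotype_states
#' @title Genotype state vocabulary
#' @description
#' Genotype calls use a fixed four-level vocabulary:
#' `"biallelic_loss"` (homozygous deletion / biallelic inactivation;
#' "deficient" for RB1), `"altered"` (biallelic inactivation or
#' gain-of-function mutation; used for TP53 and for loss-of-function flags on
#' repair genes), `"monoallelic_or_wt"` (single-copy loss or wild-type) and
#' `"wt"`. Loss of function means `biallelic_loss` or `altered`; TP53 is
#' "wild-type-like" for the nonresponder rule when `monoallelic_or_wt` or
#' `wt`.
NULL

GENOTYPE_STATES <- c("biallelic_loss", "altered", "monoallelic_or_wt", "wt")

genotype_is_lof <- function(state) state %in% c("biallelic_loss", "altered")
genotype_is_wt_like <- function(state) state %in% c("monoallelic_or_wt", "wt")

check_genotype_state <- function(state, gene) {
  if (is.null(state) || length(state) != 1L || is.na(state) ||
      !state %in% GENOTYPE_STATES)
    stop_("missing or invalid ", gene, " genotype state (need one of: ",
          paste(GENOTYPE_STATES, collapse = ", "), ")")
  state
}

#' Thresholds for the composite biomarker classifier
#'
#' @param repstress_z z-scale replication-stress score above which an
#'   RB1-wild-type model is treated as replication-stressed (default +1, a
#'   conservative cutoff for "above average").
#' @param nauc_responder nAUC responder cutoff carried in provenance.
#' @param hscore_cutoff IHC H-score positivity cutoff carried in provenance.
#' @return named list of thresholds.
#' @export
classifier_thresholds <- function(repstress_z = 1, nauc_responder = 0.75,
                                  hscore_cutoff = 20) {
  list(repstress_z = repstress_z, nauc_responder = nauc_responder,
       hscore_cutoff = hscore_cutoff)
}

#' Composite biomarker call for one model
#'
#' Deterministic, ordered decision rules mapping a model's B7H3 status,
#' genotypes, replication-stress score and SLFN11 status to a predicted
#' B7H3-PBD-ADC response class. Exactly one rule fires:
#'
#' 1. B7H3 not expressed -> `ineligible` (target expression is necessary);
#' 2. RB1 biallelic loss OR replication-stress z-score above threshold ->
#'    `responder` (replication stress predicts sensitivity independently of
#'    SLFN11);
#' 3. SLFN11 expressed -> `responder`;
#' 4. ATR or CHD1 loss of function -> `responder` (crosslink-repair
#'    deficiency);
#' 5. TP53 wild-type -> `nonresponder`;
#' 6. otherwise `indeterminate` (TP53-altered with no positive biomarker is
#'    left uncalled).
#'
#' BRCA2 state is carried in annotations but deliberately fires no rule:
#' BRCA2-deficient/TP53-wild-type models have been observed nonresponsive,
#' and the TP53 rule dominates.
#'
#' @param annotation one-row data.frame or list with `model_id`,
#'   `b7h3_positive` (logical), genotype states `RB1`, `TP53` (required) and
#'   optionally `ATR`, `CHD1` (default `"wt"`), `slfn11` (logical, default
#'   FALSE), `repstress_z` (numeric, NA ignored).
#' @param thresholds a [classifier_thresholds()] list.
#' @return one-row data.frame: `model_id`, `predicted`
#'   (`responder`/`nonresponder`/`ineligible`/`indeterminate`),
#'   `rule_fired`, `rationale`.
#' @export
classify_model <- function(annotation, thresholds = classifier_thresholds()) {
  a <- as.list(annotation)
  rb1 <- check_genotype_state(a$RB1, "RB1")
  tp53 <- check_genotype_state(a$TP53, "TP53")
  atr <- a$ATR %||% "wt"
  chd1 <- a$CHD1 %||% "wt"
  slfn11 <- isTRUE(a$slfn11)
  rsz <- a$repstress_z %||% NA_real_
  b7h3 <- a$b7h3_positive
  if (is.null(b7h3) || is.na(b7h3)) stop_("b7h3_positive flag is required")

  call <- function(predicted, rule, rationale) {
    data.frame(model_id = a$model_id %||% NA_character_,
               predicted = predicted, rule_fired = rule,
               rationale = rationale, stringsAsFactors = FALSE)
  }

  if (!isTRUE(b7h3))
    return(call("ineligible", "b7h3_negative",
                "B7H3 not expressed: target antigen required for ADC delivery"))
  if (rb1 == "biallelic_loss")
    return(call("responder", "rb1_loss_or_repstress", "RB1 biallelic loss"))
  if (!is.na(rsz) && rsz > thresholds$repstress_z)
    return(call("responder", "rb1_loss_or_repstress",
                sprintf("RepStress z = %.2f above threshold %.2f",
                        rsz, thresholds$repstress_z)))
  if (slfn11)
    return(call("responder", "slfn11_positive", "SLFN11 expressed"))
  if (genotype_is_lof(atr))
    return(call("responder", "dna_repair_loss", "ATR loss of function"))
  if (genotype_is_lof(chd1))
    return(call("responder", "dna_repair_loss", "CHD1 loss of function"))
  if (genotype_is_wt_like(tp53))
    return(call("nonresponder", "tp53_wt",
                "TP53 wild-type with no sensitizing biomarker"))
  call("indeterminate", "no_biomarker",
       "TP53 altered but no positive biomarker")
}

#' Classify every model in an annotation table
#'
#' @param annotations data.frame with one row per model (columns as in
#'   [classify_model()]).
#' @param thresholds a [classifier_thresholds()] list.
#' @return data.frame of calls, one row per model.
#' @export
classify_models <- function(annotations,
                            thresholds = classifier_thresholds()) {
  stopifnot(is.data.frame(annotations), nrow(annotations) >= 1L)
  out <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    classify_model(annotations[i, , drop = FALSE], thresholds)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate biomarker calls against observed responses
#'
#' Confronts predicted classes with observed responder/nonresponder labels
#' over eligible models, and reports the named biomarker tallies used to
#' summarize the model panel: SLFN11+ adenocarcinoma (ARPC) responders,
#' SLFN11- ARPC responders and their denominator, SLFN11- nonresponders with
#' wild-type-like TP53, RB1-deficient models that are SLFN11+, and ARPC
#' nonresponders.
#'
#' @param calls data.frame from [classify_models()].
#' @param annotations annotation data.frame with `model_id`, `phenotype`,
#'   `slfn11`, genotype states and `observed_response`
#'   (`"R"`/`"NR"`/`NA`).
#' @return list of class `call_evaluation` with `confusion` (predicted x
#'   observed over eligible, observed-labelled models), `counts` (named
#'   numerator/denominator tallies) and `accuracy` (over models with a
#'   decided prediction and an observed label).
#' @export
evaluate_calls <- function(calls, annotations) {
  if (anyDuplicated(calls$model_id) || anyDuplicated(annotations$model_id))
    stop_("duplicated model_id")
  merged <- merge(calls, annotations, by = "model_id", sort = FALSE)

  obs <- merged$observed_response
  eligible <- merged$predicted != "ineligible" & !is.na(obs) & obs != "NA"
  ev <- merged[eligible, , drop = FALSE]
  confusion <- table(
    predicted = factor(ev$predicted,
                       levels = c("responder", "nonresponder",
                                  "indeterminate")),
    observed = factor(ev$observed_response, levels = c("R", "NR")))

  ann <- annotations
  is_r <- !is.na(ann$observed_response) & ann$observed_response == "R"
  is_nr <- !is.na(ann$observed_response) & ann$observed_response == "NR"
  arpc <- ann$phenotype == "ARPC"
  slfn <- as.logical(ann$slfn11)
  rb1_def <- ann$RB1 == "biallelic_loss"
  tp53_wt <- genotype_is_wt_like(ann$TP53)

  counts <- list(
    slfn11_pos_arpc = sum(arpc & slfn),
    slfn11_pos_arpc_responders = sum(arpc & slfn & is_r),
    slfn11_neg_arpc = sum(arpc & !slfn),
    slfn11_neg_arpc_responders = sum(arpc & !slfn & is_r),
    slfn11_neg_nonresponders = sum(!slfn & is_nr),
    slfn11_neg_nonresponders_tp53_wt = sum(!slfn & is_nr & tp53_wt),
    rb1_deficient = sum(rb1_def),
    rb1_deficient_slfn11_pos = sum(rb1_def & slfn),
    arpc_nonresponders = sum(arpc & is_nr))

  decided <- ev$predicted %in% c("responder", "nonresponder")
  acc <- if (any(decided)) {
    mean((ev$predicted[decided] == "responder") ==
           (ev$observed_response[decided] == "R"))
  } else NA_real_

  structure(list(confusion = confusion, counts = counts, accuracy = acc),
            class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat("<call_evaluation>\n")
  print(x$confusion)
  cat(sprintf("accuracy (decided calls): %s\n",
              ifelse(is.na(x$accuracy), "NA",
                     sprintf("%.3f", x$accuracy))))
  cat(sprintf("SLFN11+ ARPC responders: %d of %d\n",
              x$counts$slfn11_pos_arpc_responders, x$counts$slfn11_pos_arpc))
  cat(sprintf("SLFN11- ARPC responders: %d of %d\n",
              x$counts$slfn11_neg_arpc_responders, x$counts$slfn11_neg_arpc))
  cat(sprintf("SLFN11- nonresponders with TP53 wt: %d of %d\n",
              x$counts$slfn11_neg_nonresponders_tp53_wt,
              x$counts$slfn11_neg_nonresponders))
  cat(sprintf("RB1-deficient models SLFN11+: %d of %d\n",
              x$counts$rb1_deficient_slfn11_pos, x$counts$rb1_deficient))
  invisible(x)
}
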