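#' Assemble a pipeline configuration
#'
#' Collects file paths and every decision threshold in one validated object;
#' all thresholds are echoed into the provenance block written next to the
#' outputs, so each result records the settings that produced it.
#'
#' @param expression path to a raw-count expression TSV (optional).
#' @param gene_sets path to a GMT file (optional; required with
#'   `expression`).
#' @param annotations path to a model annotation TSV (required).
#' @param dose_response path to a long-format dose-response CSV (optional).
#' @param cohort path to a clinical cohort CSV (optional).
#' @param ihc path to an IHC core CSV (optional).
#' @param out_dir output directory.
#' @param seed integer seed recorded in provenance and used for any
#'   stochastic step.
#' @param thresholds a [classifier_thresholds()] list.
#' @param min_tumor_content funnel tumor-content minimum (default 0.30).
#' @param slfn11_method `"mixture"` or `"threshold"` for cohort SLFN11
#'   calling.
#' @param slfn11_threshold cutoff when `slfn11_method = "threshold"`.
#' @param repstress_signature name of the gene set whose z-score feeds the
#'   classifier's replication-stress rule (default `"RepStress"`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations, expression = NULL, gene_sets = NULL,
                            dose_response = NULL, cohort = NULL, ihc = NULL,
                            out_dir = "adcstratify_out", seed = 1L,
                            thresholds = classifier_thresholds(),
                            min_tumor_content = 0.30,
                            slfn11_method = c("mixture", "threshold"),
                            slfn11_threshold = NULL,
                            repstress_signature = "RepStress") {
  slfn11_method <- match.arg(slfn11_method)
  if (!is.null(expression) && is.null(gene_sets))
    stop_("gene_sets (GMT) required when expression is supplied")
  structure(list(annotations = annotations, expression = expression,
                 gene_sets = gene_sets, dose_response = dose_response,
                 cohort = cohort, ihc = ihc, out_dir = out_dir,
                 seed = as.integer(seed), thresholds = thresholds,
                 min_tumor_content = min_tumor_content,
                 slfn11_method = slfn11_method,
                 slfn11_threshold = slfn11_threshold,
                 repstress_signature = repstress_signature),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full stratification pipeline
#'
#' Executes, in order: expression normalization (TMM to log2 CPM) and
#' signature scoring (when expression + gene sets are supplied, with the
#' replication-stress z-score merged into the annotations), composite
#' biomarker classification and evaluation against observed responses;
#' optionally dose-response summarization, cohort funnel stratification and
#' TMA summarization. All referenced inputs are checked before anything is
#' written; any stage failure aborts with the stage name, and no output file
#' is left behind partially written (every writer is atomic). A provenance
#' JSON recording package version, seed, thresholds and input MD5 digests is
#' always emitted.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `annotations`, `scores`,
#'   `calls`, `evaluation`, and (when inputs were supplied)
#'   `dose_response`, `funnel`, `tma`; plus `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- Filter(Negate(is.null),
                   config[c("annotations", "expression", "gene_sets",
                            "dose_response", "cohort", "ihc")])
  missing <- unlist(inputs)[!file.exists(unlist(inputs))]
  if (length(missing))
    stop_("missing input file(s): ", paste(missing, collapse = ", "))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  ann <- run_stage("annotations", read_model_annotations(config$annotations))

  scores <- NULL
  if (!is.null(config$expression)) {
    scores <- run_stage("signatures", {
      counts <- read_expression(config$expression, "raw_counts")
      sets <- read_gmt(config$gene_sets)
      norm <- tmm_normalize(counts)
      z_transform(ssgsea_score(norm$logcpm, sets))
    })
    if (config$repstress_signature %in% rownames(scores$z)) {
      idx <- match(ann$model_id, colnames(scores$z))
      ann$repstress_z <- scores$z[config$repstress_signature, idx]
    }
    run_stage("signatures", atomic_write(out("scores.tsv"), function(tmp) {
      df <- data.frame(signature = rownames(scores$raw),
                       scores$raw, check.names = FALSE)
      utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }))
  }

  calls <- run_stage("classify", classify_models(ann, config$thresholds))
  run_stage("classify", atomic_write(out("calls.tsv"), function(tmp) {
    utils::write.table(calls, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }))
  evaluation <- if (!is.null(ann$observed_response) &&
                    any(!is.na(ann$observed_response)))
    run_stage("evaluate", evaluate_calls(calls, ann)) else NULL

  dr <- NULL
  if (!is.null(config$dose_response)) {
    dr <- run_stage("dose_response", {
      curves <- read_dose_response(config$dose_response)
      lapply(curves, function(m)
        compute_nauc(m$targeted, m$control,
                     config$thresholds$nauc_responder))
    })
    run_stage("dose_response",
              write_dose_response_summary(dr, out("dose_response.tsv")))
  }

  funnel <- NULL
  if (!is.null(config$cohort)) {
    funnel <- run_stage("funnel", {
      cohort <- filter_tumor_content(read_cohort(config$cohort),
                                     config$min_tumor_content)
      caller <- if (config$slfn11_method == "threshold")
        function(x) call_slfn11(x, "threshold",
                                threshold = config$slfn11_threshold)$status
      else function(x) call_slfn11(x, "mixture")$status
      run_funnel(cohort, caller)
    })
    run_stage("funnel", atomic_write(out("funnel.tsv"), function(tmp) {
      utils::write.table(funnel$stages, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }))
  }

  tma <- NULL
  if (!is.null(config$ihc)) {
    tma <- run_stage("histology", {
      summarize_tma(average_cores(read_ihc_cores(config$ihc)),
                    config$thresholds$hscore_cutoff)
    })
  }

  provenance <- list(
    package = "adcstratify",
    version = as.character(utils::packageVersion("adcstratify")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    thresholds = config$thresholds,
    min_tumor_content = config$min_tumor_content,
    slfn11_method = config$slfn11_method,
    slfn11_threshold = config$slfn11_threshold,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  atomic_write(out("provenance.json"), function(tmp) {
    jsonlite::write_json(provenance, tmp, auto_unbox = TRUE, pretty = TRUE)
  })

  structure(list(annotations = ann, scores = scores, calls = calls,
                 evaluation = evaluation, dose_response = dr,
                 funnel = funnel, tma = tma, provenance = provenance),
            class = "pipeline_result")
}
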