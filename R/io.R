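#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, then member genes.
#' Duplicate members are de-duplicated with a warning; a line with fewer
#' than 3 fields or an empty member list is an error naming the line.
#'
#' @param path file path.
#' @return list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop_("malformed GMT line ", i, ": fewer than 3 fields")
    gene_set(f[1], f[-(1:2)], f[2])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects.
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(vapply(sets, inherits, TRUE, "gene_set")))
  atomic_write(path, function(tmp) {
    lines <- vapply(sets, function(s) {
      desc <- if (nzchar(s$description)) s$description else "na"
      paste(c(s$name, desc, s$genes), collapse = "\t")
    }, "")
    writeLines(lines, tmp)
  })
}

#' Read a gene-by-sample expression TSV
#'
#' Genes as rows (first column), samples as columns. The normalization scale
#' is not inferable from the file and must be declared by the caller.
#'
#' @param path file path.
#' @param scale scale to record (see [expression_matrix()]).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale) {
  if (!file.exists(path)) stop_("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    stop_("duplicated gene id(s): ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    suppressWarnings(num <- as.numeric(vals[[j]]))
    bad <- which(is.na(num) & !is.na(vals[[j]]))
    if (length(bad))
      stop_("non-numeric value at gene '", genes[bad[1]], "', sample '",
            names(vals)[j], "'")
    vals[[j]] <- num
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, scale)
}

#' Write an expression matrix as TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_expression <- function(em, path) {
  atomic_write(path, function(tmp) {
    df <- data.frame(gene = rownames(em), unclass(em), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
}

#' Flatten dose-response experiments to a long-format table
#'
#' @param experiments a list of [dr_experiment()] objects (nested lists are
#'   flattened).
#' @return data.frame with columns `model`, `agent`, `experiment`, `dose`,
#'   `replicate`, `viability`, `unit`.
#' @export
dose_response_table <- function(experiments) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "dr_experiment")) flat[[length(flat) + 1L]] <<- x
    else lapply(x, collect)
  }
  collect(experiments)
  do.call(rbind, lapply(flat, function(e) {
    reps <- ncol(e$viability)
    data.frame(model = e$model_id, agent = e$agent,
               experiment = e$experiment_id,
               dose = rep(e$doses, reps),
               replicate = rep(seq_len(reps), each = length(e$doses)),
               viability = as.vector(e$viability),
               unit = "ug/mL", stringsAsFactors = FALSE)
  }))
}

#' Read long-format dose-response curves from CSV
#'
#' Expected columns: `model`, `agent` (`targeted`/`control`), `experiment`,
#' `dose`, `replicate`, `viability`, and optionally `unit` (`ng/mL` values
#' are converted to `ug/mL`).
#'
#' @param path CSV path.
#' @return named list per model, each with `targeted` and `control` lists of
#'   [dr_experiment()] objects.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "agent", "experiment", "dose", "replicate", "viability")
  if (!all(need %in% names(tab)))
    stop_("dose-response CSV must have columns: ",
          paste(need, collapse = ", "))
  if (!is.null(tab$unit)) {
    bad <- !tab$unit %in% c("ng/mL", "ug/mL", "µg/mL")
    if (any(bad)) stop_("unsupported dose unit(s): ",
                        paste(unique(tab$unit[bad]), collapse = ", "))
    tab$dose <- ifelse(tab$unit == "ng/mL", tab$dose / 1000, tab$dose)
  }
  out <- lapply(split(tab, tab$model), function(mt) {
    by_agent <- lapply(split(mt, mt$agent), function(at) {
      lapply(split(at, at$experiment), function(et) {
        et <- et[order(et$dose, et$replicate), ]
        doses <- sort(unique(et$dose))
        reps <- sort(unique(et$replicate))
        v <- matrix(NA_real_, length(doses), length(reps))
        v[cbind(match(et$dose, doses), match(et$replicate, reps))] <-
          et$viability
        dr_experiment(mt$model[1], at$agent[1], doses, v, et$experiment[1])
      })
    })
    list(targeted = unname(by_agent$targeted),
         control = unname(by_agent$control))
  })
  out
}

#' Write per-model dose-response summaries as TSV
#'
#' @param summaries list of `dose_response_summary` objects.
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_dose_response_summary <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(model_id = s$model_id, nauc_median = s$nauc_median,
               nauc_iqr = s$nauc_iqr, ic50 = s$ic50, maxr = s$maxr,
               responder = s$responder, stringsAsFactors = FALSE)
  }))
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read / write model annotation tables (TSV)
#'
#' Annotation tables mirror the model-panel layout: one row per model with
#' phenotype, B7H3 level/status, genotype states, SLFN11 status, signature
#' z-scores and observed response.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_model_annotations <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("model_id", "RB1", "TP53") %in% names(tab)))
    stop_("annotation table needs at least model_id, RB1, TP53")
  if (!is.null(tab$slfn11)) tab$slfn11 <- as.logical(tab$slfn11)
  if (!is.null(tab$b7h3_positive))
    tab$b7h3_positive <- as.logical(tab$b7h3_positive)
  tab
}

#' @rdname read_model_annotations
#' @param annotations data.frame to write.
#' @export
write_model_annotations <- function(annotations, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(annotations, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
}

#' Read / write cohort tables (CSV)
#'
#' @param path file path.
#' @return data.frame with at least `sample_id`, `tumor_content` and the
#'   genotype-state columns used by [run_funnel()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_cohort
#' @param cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(cohort, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Read / write IHC core tables (CSV)
#'
#' @param path file path.
#' @return data.frame as accepted by [hscore_cores()].
#' @export
read_ihc_cores <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "core_id", paste0("pct", 0:3))
  if (!all(need %in% names(tab)))
    stop_("IHC core CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(tab$evaluable)) tab$evaluable <- as.logical(tab$evaluable)
  tab
}

#' @rdname read_ihc_cores
#' @param cores data.frame to write.
#' @export
write_ihc_cores <- function(cores, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(cores, tmp, row.names = FALSE, quote = FALSE)
  })
}
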