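#' Four-parameter logistic viability curve
#'
#' Percent viability as a decreasing Hill function of dose:
#' \deqn{v(d) = bottom + (top - bottom) / (1 + (d / ic50)^{slope})}
#' with `slope > 0` giving a curve falling from `top` at low dose to
#' `bottom` at high dose, crossing the midpoint at `ic50`.
#'
#' @param dose positive concentrations (ug/mL).
#' @param top,bottom asymptotic viability (%) at low and high dose.
#' @param ic50 dose at half-maximal effect (same units as `dose`).
#' @param slope Hill slope (dimensionless, > 0 for a decreasing curve).
#' @return numeric vector of viabilities.
#' @export
four_pl <- function(dose, top, bottom, ic50, slope) {
  bottom + (top - bottom) / (1 + (dose / ic50)^slope)
}

#' Construct a dose-response experiment
#'
#' One biologically independent run of the ex vivo organoid viability assay:
#' a set of ascending doses of one agent (the targeted ADC or its non-binding
#' isotype control) with replicate percent-viability readings per dose.
#'
#' @param model_id model identifier.
#' @param agent `"targeted"` or `"control"`.
#' @param doses strictly increasing positive concentrations in ug/mL.
#' @param viability numeric matrix, one row per dose, one column per replicate;
#'   a vector is taken as a single replicate. Values are percent viability
#'   relative to untreated and may exceed 100; they must be nonnegative.
#' @param experiment_id batch identifier used to pair targeted and control
#'   runs from the same experiment.
#' @return an object of class `dr_experiment`.
#' @export
dr_experiment <- function(model_id, agent, doses, viability,
                          experiment_id = "exp1") {
  agent <- match.arg(agent, c("targeted", "control"))
  doses <- as.numeric(doses)
  if (length(doses) < 2L) stop_("need at least 2 dose levels")
  if (any(!is.finite(doses)) || any(doses <= 0)) stop_("doses must be positive")
  if (any(diff(doses) <= 0)) stop_("doses must be strictly increasing")
  if (is.null(dim(viability))) viability <- matrix(viability, ncol = 1L)
  viability <- as.matrix(viability)
  if (nrow(viability) != length(doses))
    stop_("viability must have one row per dose")
  if (any(!is.finite(viability)) || any(viability < 0))
    stop_("viability must be finite and nonnegative")
  structure(list(model_id = model_id, agent = agent, doses = doses,
                 viability = viability, experiment_id = experiment_id),
            class = "dr_experiment")
}

#' @export
print.dr_experiment <- function(x, ...) {
  cat(sprintf("<dr_experiment> %s / %s (%s): %d doses x %d replicates\n",
              x$model_id, x$agent, x$experiment_id,
              length(x$doses), ncol(x$viability)))
  invisible(x)
}

#' Fit a four-parameter logistic to a dose-response experiment
#'
#' Least-squares 4PL fit (Levenberg-Marquardt) of mean viability against
#' log10 dose. The IC50 is the relative (curve midpoint) IC50. A flat curve
#' or an optimizer failure yields `converged = FALSE`, never an error; an
#' IC50 estimate outside the tested dose range is flagged via
#' `ic50_in_range = FALSE` and should not be interpreted numerically.
#'
#' @param experiment a [dr_experiment()].
#' @return list of class `four_pl_fit` with elements `top`, `bottom`, `ic50`,
#'   `slope`, `converged`, `ic50_in_range`, `rss`.
#' @export
fit_4pl <- function(experiment) {
  stopifnot(inherits(experiment, "dr_experiment"))
  doses <- experiment$doses
  if (length(doses) < 4L) stop_("fit_4pl needs at least 4 dose levels")
  mv <- rowMeans(experiment$viability)
  if (any(!is.finite(mv))) stop_("non-finite mean viability")
  failed <- structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                           slope = NA_real_, converged = FALSE,
                           ic50_in_range = FALSE, rss = NA_real_),
                      class = "four_pl_fit")
  if (diff(range(mv)) < 1e-8) return(failed)  # flat curve: no information

  ld <- log10(doses)
  mid <- ld[which.min(abs(mv - (max(mv) + min(mv)) / 2))]
  # a small ladder of starts guards against unlucky initial Jacobians
  starts <- list(
    list(top = max(mv), bottom = min(mv), logic50 = mid, slope = 1),
    list(top = max(mv), bottom = min(mv), logic50 = mid, slope = 1.5),
    list(top = max(mv), bottom = min(mv), logic50 = mean(range(ld)),
         slope = 0.8))
  fit <- NULL
  for (start in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        mv ~ bottom + (top - bottom) / (1 + 10^((ld - logic50) * slope)),
        start = start,
        lower = c(top = -Inf, bottom = -Inf, logic50 = min(ld) - 6,
                  slope = 1e-3),
        upper = c(top = Inf, bottom = Inf, logic50 = max(ld) + 6,
                  slope = 100),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)))
      fit <- cand
  }
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["top"]] < cf[["bottom"]]) return(failed)
  ic50 <- 10^cf[["logic50"]]
  structure(list(top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
                 ic50 = ic50, slope = unname(cf[["slope"]]), converged = TRUE,
                 ic50_in_range = ic50 >= min(doses) && ic50 <= max(doses),
                 rss = sum(stats::resid(fit)^2)),
            class = "four_pl_fit")
}

#' Normalized area under a dose-response curve
#'
#' Replicates are averaged per dose, then mean viability is integrated by the
#' trapezoidal rule over log10(dose) and divided by `100 * span(log10 dose)`.
#' A curve at a constant 100% viability therefore scores exactly 1, and the
#' statistic is invariant to rescaling all doses by a constant.
#'
#' @param experiment a [dr_experiment()].
#' @return nonnegative dimensionless AUC.
#' @export
compute_auc <- function(experiment) {
  stopifnot(inherits(experiment, "dr_experiment"))
  doses <- experiment$doses
  if (length(doses) < 2L) stop_("compute_auc needs at least 2 dose levels")
  mv <- rowMeans(experiment$viability)
  x <- log10(doses)
  pracma::trapz(x, mv) / (100 * (max(x) - min(x)))
}

#' Normalized AUC (nAUC) summary for one model
#'
#' For each experiment (paired by `experiment_id`), nAUC is the ratio of the
#' targeted-agent AUC to the control-agent AUC; the per-model summary is the
#' median nAUC across experiments with its interquartile range. The median is
#' the statistic used for all downstream analysis. IC50 (median over
#' converged, in-range per-experiment 4PL fits) and MaxR (median of mean
#' viability at the top dose of the targeted agent) are carried along, and a
#' responder call is made on the median nAUC.
#'
#' @param targeted,control lists of [dr_experiment()] (a bare experiment is
#'   accepted), paired one-to-one by `experiment_id`.
#' @param responder_threshold nAUC cutoff passed to [call_responder()].
#' @return list of class `dose_response_summary` with `model_id`,
#'   `nauc_median`, `nauc_iqr`, `per_experiment_nauc`, `ic50`, `maxr`,
#'   `responder`, `responder_threshold`.
#' @export
compute_nauc <- function(targeted, control, responder_threshold = 0.75) {
  as_list <- function(x) if (inherits(x, "dr_experiment")) list(x) else x
  targeted <- as_list(targeted); control <- as_list(control)
  if (length(targeted) < 1L) stop_("need at least one targeted experiment")
  tid <- vapply(targeted, `[[`, "", "experiment_id")
  cid <- vapply(control, `[[`, "", "experiment_id")
  unpaired <- c(setdiff(tid, cid), setdiff(cid, tid))
  if (length(unpaired))
    stop_("unpaired experiment ids: ", paste(unique(unpaired), collapse = ", "))
  control <- control[match(tid, cid)]

  nauc <- vapply(seq_along(targeted), function(i) {
    ac <- compute_auc(control[[i]])
    if (ac == 0) stop_("degenerate control curve (AUC = 0) in experiment ",
                       tid[i])
    compute_auc(targeted[[i]]) / ac
  }, numeric(1))
  names(nauc) <- tid

  ic50s <- vapply(targeted, function(e) {
    f <- tryCatch(fit_4pl(e), error = function(err) NULL)
    if (!is.null(f) && f$converged && f$ic50_in_range) f$ic50 else NA_real_
  }, numeric(1))
  maxr <- stats::median(vapply(targeted, function(e) {
    mean(e$viability[length(e$doses), ])
  }, numeric(1)))

  med <- stats::median(nauc)
  structure(list(
    model_id = targeted[[1]]$model_id,
    nauc_median = med,
    nauc_iqr = stats::IQR(nauc),
    per_experiment_nauc = nauc,
    ic50 = if (all(is.na(ic50s))) NA_real_ else
      stats::median(ic50s, na.rm = TRUE),
    maxr = maxr,
    responder = call_responder(med, responder_threshold),
    responder_threshold = responder_threshold),
    class = "dose_response_summary")
}

#' @export
print.dose_response_summary <- function(x, ...) {
  cat(sprintf(
    "<dose_response_summary> %s: median nAUC %.3f (IQR %.3f, n=%d), IC50 %s ug/mL, MaxR %.1f%% -> %s\n",
    x$model_id, x$nauc_median, x$nauc_iqr, length(x$per_experiment_nauc),
    ifelse(is.na(x$ic50), "NA", format(x$ic50, digits = 3)), x$maxr,
    x$responder))
  invisible(x)
}

#' Call responder status from a median nAUC
#'
#' A model is a responder (`"R"`) iff its median nAUC is strictly below the
#' threshold, else a nonresponder (`"NR"`). The cutoff is a reproduction aid:
#' when observed response labels exist they take precedence downstream.
#'
#' @param summary a `dose_response_summary` or a bare median-nAUC value.
#' @param threshold positive nAUC cutoff (default 0.75).
#' @return `"R"` or `"NR"`.
#' @export
call_responder <- function(summary, threshold = 0.75) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_("threshold must be a single positive number")
  nauc <- if (inherits(summary, "dose_response_summary"))
    summary$nauc_median else summary
  stopifnot(is.numeric(nauc), length(nauc) == 1L, is.finite(nauc))
  if (nauc < threshold) "R" else "NR"
}
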