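#' Configuration for the synthetic-data generators
#'
#' One object holds every knob of the synthetic inputs: gene-by-sample count
#' matrices with planted gene-set shifts, Hill-curve viability assays with
#' replicate noise, clinical cohorts with genotype frequencies and a bimodal
#' SLFN11 mixture, and IHC intensity tables. A single global `seed` is split
#' into independent per-generator substreams so that adding one generator
#' does not perturb the draws of another.
#'
#' Defaults emulate the study conditions the pipeline assumes: 5 replicate
#' wells and 3 independent experiments per dose-response assay on a
#' seven-point serial dilution up to 4 ug/mL; negative-binomial counts
#' (dispersion 0.1, the standard bulk RNA-seq assumption); additive Gaussian
#' viability noise of 5% truncated at 0 (values above 100% are allowed, as
#' viability is relative to control); cohort genotype frequencies of 10%
#' RB1 homozygous loss, ~40% TP53 alteration and 2% each ATR/CHD1 loss; and
#' a two-component SLFN11 mixture with a 40% expressing fraction.
#'
#' @param seed integer global seed.
#' @param n_genes,n_samples dimensions of the simulated expression matrix.
#' @param planted_sets list of planted signals, each a list with `name`,
#'   `genes` (character, members of the simulated gene universe), `delta`
#'   (log2 shift) and `fraction` (affected-sample fraction in [0, 1]).
#' @param slfn11_mixture named numeric: `low_mean`, `high_mean`, `sd`,
#'   `positive_fraction` of the SLFN11 expression mixture.
#' @param genotype_freqs named fractions of altered samples per gene; the
#'   cohort generator requires `RB1`, `TP53`, `ATR`, `CHD1`.
#' @param hill_params named list per model of `c(top, bottom, ic50, slope)`
#'   for the targeted-agent viability curve (ic50 in ug/mL).
#' @param control_hill the control-agent curve (default flat at 100%).
#' @param dose_grid strictly increasing positive concentrations (ug/mL).
#' @param replicates replicate wells per dose (>= 1).
#' @param n_experiments independent experiments per model.
#' @param noise_sd viability noise standard deviation (%; >= 0).
#' @param dispersion negative-binomial dispersion of the counts (0 =
#'   Poisson).
#' @param base_log2_mean,base_log2_sd log2-scale location and spread of the
#'   simulated gene means.
#' @param cohort_size number of samples drawn by [simulate_cohort()].
#' @param ihc_profiles list of length-4 intensity-percentage vectors (each
#'   summing to 100), one tumor generated per profile.
#' @param ihc_concentration Dirichlet concentration of core-to-core
#'   variation around each profile (larger = tighter).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_samples = 40L,
                              planted_sets = list(),
                              slfn11_mixture = c(low_mean = 2, high_mean = 6,
                                                 sd = 1,
                                                 positive_fraction = 0.40),
                              genotype_freqs = c(RB1 = 0.10, TP53 = 0.405,
                                                 ATR = 0.02, CHD1 = 0.02),
                              hill_params = list(),
                              control_hill = c(top = 100, bottom = 100,
                                               ic50 = 1, slope = 1),
                              dose_grid = 4 * 10^seq(-6, 0, by = 1),
                              replicates = 5L,
                              n_experiments = 3L,
                              noise_sd = 5,
                              dispersion = 0.1,
                              base_log2_mean = 5,
                              base_log2_sd = 2,
                              cohort_size = 10000L,
                              ihc_profiles = list(),
                              ihc_concentration = 500) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_samples = n_samples, planted_sets = planted_sets,
              slfn11_mixture = slfn11_mixture,
              genotype_freqs = genotype_freqs, hill_params = hill_params,
              control_hill = control_hill, dose_grid = dose_grid,
              replicates = replicates, n_experiments = n_experiments,
              noise_sd = noise_sd, dispersion = dispersion,
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              cohort_size = cohort_size, ihc_profiles = ihc_profiles,
              ihc_concentration = ihc_concentration)

  if (!is_count(cfg$n_genes) || !is_count(cfg$n_samples))
    stop_("n_genes and n_samples must be positive integers")
  for (ps in cfg$planted_sets) {
    if (!all(c("name", "genes", "delta", "fraction") %in% names(ps)))
      stop_("each planted set needs name, genes, delta, fraction")
    if (!is_fraction(ps$fraction)) stop_("planted fraction must be in [0, 1]")
  }
  mix <- cfg$slfn11_mixture
  if (!all(c("low_mean", "high_mean", "sd", "positive_fraction") %in%
           names(mix)))
    stop_("slfn11_mixture needs low_mean, high_mean, sd, positive_fraction")
  if (!is_fraction(mix[["positive_fraction"]]) || mix[["sd"]] <= 0)
    stop_("invalid slfn11_mixture parameters")
  if (!is_fraction(cfg$genotype_freqs))
    stop_("genotype_freqs must be fractions in [0, 1]")
  if (any(cfg$dose_grid <= 0) || any(diff(cfg$dose_grid) <= 0))
    stop_("dose_grid must be strictly increasing and positive")
  if (!is_count(cfg$replicates)) stop_("replicates must be >= 1")
  if (!is_count(cfg$n_experiments)) stop_("n_experiments must be >= 1")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    stop_("noise_sd must be >= 0")
  if (cfg$dispersion < 0) stop_("dispersion must be >= 0")
  for (p in cfg$ihc_profiles) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 100) > 1e-6)
      stop_("each ihc profile must be 4 nonnegative percentages summing to 100")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a raw-count expression matrix with planted gene-set shifts
#'
#' Gene means are drawn log-normally, counts negative-binomially around
#' them. For each planted set, a random `fraction` of samples has the member
#' genes' log2 means shifted by `delta`; the returned truth table records
#' which samples carry which signal, so downstream signature scoring can be
#' validated against ground truth.
#'
#' @param config a [simulation_config()]; planted-set genes must name genes
#'   of the simulated universe `g0001`, `g0002`, ...
#' @return list with `counts` (an [expression_matrix()] of raw counts) and
#'   `truth` (samples x planted-sets logical matrix).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stream_seed(config$seed, "expression"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  samples <- sprintf("s%03d", seq_len(config$n_samples))

  for (ps in config$planted_sets) {
    unknown <- setdiff(ps$genes, genes)
    if (length(unknown))
      stop_("planted set '", ps$name, "' references unknown genes: ",
            paste(unknown, collapse = ", "))
  }

  base_log2 <- stats::rnorm(config$n_genes, config$base_log2_mean,
                            config$base_log2_sd)
  log2_mu <- matrix(base_log2, nrow = config$n_genes,
                    ncol = config$n_samples,
                    dimnames = list(genes, samples))

  truth <- matrix(FALSE, nrow = config$n_samples,
                  ncol = length(config$planted_sets),
                  dimnames = list(samples,
                                  vapply(config$planted_sets, `[[`, "",
                                         "name")))
  for (k in seq_along(config$planted_sets)) {
    ps <- config$planted_sets[[k]]
    n_aff <- round(ps$fraction * config$n_samples)
    aff <- sample(samples, n_aff)
    truth[aff, k] <- TRUE
    log2_mu[ps$genes, aff] <- log2_mu[ps$genes, aff] + ps$delta
  }

  mu <- 2^log2_mu
  counts <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow = config$n_genes, dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu),
           nrow = config$n_genes, dimnames = dimnames(mu))
  }
  list(counts = expression_matrix(counts, "raw_counts"), truth = truth)
}

#' Simulate paired targeted/control dose-response experiments
#'
#' Targeted-agent viability follows the model's four-parameter logistic
#' curve ([four_pl()]); the control agent follows `control_hill` (flat at
#' ~100% by default). Gaussian noise of `noise_sd` percent is added per well
#' and truncated at 0 (not above 100, since viability is relative to
#' untreated control and can exceed it).
#'
#' @param config a [simulation_config()] with `hill_params[[model_id]]`
#'   defined.
#' @param model_id model to simulate.
#' @return list with `targeted` and `control`, each a list of
#'   `config$n_experiments` [dr_experiment()] objects with matching
#'   `experiment_id`s.
#' @export
simulate_dose_response <- function(config, model_id) {
  stopifnot(inherits(config, "simulation_config"))
  hp <- config$hill_params[[model_id]]
  if (is.null(hp)) stop_("no hill_params for model ", model_id)
  set.seed(stream_seed(config$seed, "dose_response"))
  draw_curve <- function(params) {
    mu <- four_pl(config$dose_grid, params[["top"]], params[["bottom"]],
                  params[["ic50"]], params[["slope"]])
    v <- matrix(stats::rnorm(length(config$dose_grid) * config$replicates,
                             mean = rep(mu, config$replicates),
                             sd = config$noise_sd),
                nrow = length(config$dose_grid))
    pmax(v, 0)
  }
  eids <- sprintf("exp%d", seq_len(config$n_experiments))
  targeted <- lapply(eids, function(e)
    dr_experiment(model_id, "targeted", config$dose_grid, draw_curve(hp), e))
  control <- lapply(eids, function(e)
    dr_experiment(model_id, "control", config$dose_grid,
                  draw_curve(config$control_hill), e))
  list(targeted = targeted, control = control)
}

#' Simulate a clinical cohort table
#'
#' Draws `config$cohort_size` samples with Beta-distributed tumor content,
#' independent Bernoulli genotype states at the configured frequencies (RB1
#' as homozygous/biallelic loss, TP53/ATR/CHD1 as altered) and SLFN11
#' expression from the two-component Gaussian mixture.
#'
#' @param config a [simulation_config()] whose `genotype_freqs` include
#'   `RB1`, `TP53`, `ATR` and `CHD1`.
#' @param n number of samples (default `config$cohort_size`).
#' @return data.frame with `sample_id`, `patient_id`, `tumor_content`,
#'   `RB1_state`, `TP53_state`, `ATR_state`, `CHD1_state`, `SLFN11_expr`,
#'   `slfn11_truth`.
#' @export
simulate_cohort <- function(config, n = config$cohort_size) {
  stopifnot(inherits(config, "simulation_config"))
  need <- c("RB1", "TP53", "ATR", "CHD1")
  if (!all(need %in% names(config$genotype_freqs)))
    stop_("genotype_freqs must include: ", paste(need, collapse = ", "))
  set.seed(stream_seed(config$seed, "cohort"))
  gf <- config$genotype_freqs
  state <- function(gene, altered_label) {
    ifelse(stats::runif(n) < gf[[gene]], altered_label, "wt")
  }
  mix <- config$slfn11_mixture
  pos <- stats::runif(n) < mix[["positive_fraction"]]
  expr <- stats::rnorm(n,
                       mean = ifelse(pos, mix[["high_mean"]],
                                     mix[["low_mean"]]),
                       sd = mix[["sd"]])
  data.frame(
    sample_id = sprintf("c%05d", seq_len(n)),
    patient_id = sprintf("p%05d", seq_len(n)),
    tumor_content = stats::rbeta(n, 4, 3),
    RB1_state = state("RB1", "biallelic_loss"),
    TP53_state = state("TP53", "altered"),
    ATR_state = state("ATR", "altered"),
    CHD1_state = state("CHD1", "altered"),
    SLFN11_expr = expr,
    slfn11_truth = pos,
    stringsAsFactors = FALSE)
}

#' Simulate an IHC core table
#'
#' One tumor per configured intensity profile, three cores per tumor
#' (triplicates), with core-level percentages drawn from a Dirichlet
#' distribution centered on the profile (intensities with 0% stay exactly
#' 0). Percentages per core always sum to 100.
#'
#' @param config a [simulation_config()] with nonempty `ihc_profiles`.
#' @return data.frame with `tumor_id`, `core_id`, `pct0`..`pct3`,
#'   `evaluable`.
#' @export
simulate_ihc <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!length(config$ihc_profiles)) stop_("no ihc_profiles configured")
  set.seed(stream_seed(config$seed, "ihc"))
  rows <- list()
  for (i in seq_along(config$ihc_profiles)) {
    p <- config$ihc_profiles[[i]]
    alpha <- p / 100 * config$ihc_concentration
    for (core in 1:3) {
      g <- vapply(alpha, function(a) {
        if (a == 0) 0 else stats::rgamma(1, shape = a)
      }, numeric(1))
      pct <- if (sum(g) == 0) p else 100 * g / sum(g)
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = sprintf("tumor%02d", i),
        core_id = sprintf("tumor%02d_core%d", i, core),
        pct0 = pct[1], pct1 = pct[2], pct2 = pct[3], pct3 = pct[4],
        evaluable = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
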