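test_that("configuration invariants are enforced", {
  expect_error(simulation_config(dose_grid = c(1, 1, 2)), "increasing")
  expect_error(simulation_config(dose_grid = c(-1, 1)), "increasing|positive")
  expect_error(simulation_config(replicates = 0), "replicates")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(genotype_freqs = c(RB1 = 1.2)), "fraction")
  expect_error(simulation_config(ihc_profiles = list(c(50, 30, 10, 5))),
               "100")
  expect_error(simulation_config(
    planted_sets = list(list(name = "x", genes = "g1", delta = 1,
                             fraction = 2))), "fraction")
})

test_that("every generator is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 42, n_genes = 200, n_samples = 10,
                           hill_params = list(M = c(top = 100, bottom = 0,
                                                    ic50 = 0.01, slope = 1)),
                           ihc_profiles = list(c(10, 20, 30, 40)))
  e1 <- simulate_expression(cfg); e2 <- simulate_expression(cfg)
  expect_identical(e1, e2)
  d1 <- simulate_dose_response(cfg, "M")
  d2 <- simulate_dose_response(cfg, "M")
  expect_identical(d1, d2)
  expect_identical(simulate_cohort(cfg, 100), simulate_cohort(cfg, 100))
  expect_identical(simulate_ihc(cfg), simulate_ihc(cfg))
  # a different seed changes the draws
  cfg2 <- simulation_config(seed = 43, n_genes = 200, n_samples = 10)
  expect_false(identical(e1, simulate_expression(cfg2)))
})

test_that("planted shifts separate labelled samples by ssGSEA score", {
  genes <- sprintf("g%04d", 1:2000)
  set_genes <- genes[1:50]
  cfg <- simulation_config(
    seed = 5, n_genes = 2000, n_samples = 40,
    planted_sets = list(list(name = "planted", genes = set_genes,
                             delta = 2, fraction = 0.5)))
  sim <- simulate_expression(cfg)
  expect_true(all(sim$counts >= 0))
  expect_identical(sim$counts == round(sim$counts),
                   matrix(TRUE, 2000, 40, dimnames = dimnames(sim$counts)))
  logcpm <- tmm_normalize(sim$counts)$logcpm
  sc <- ssgsea_score(logcpm, gene_set("planted", set_genes))
  lab <- sim$truth[, "planted"]
  # AUROC via the rank-sum statistic
  r <- rank(sc)
  auroc <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gt(auroc, 0.95)
})

test_that("null planted sets leave signature scores exchangeable", {
  genes <- sprintf("g%04d", 1:500)
  set_genes <- genes[1:30]
  hits <- vapply(1:50, function(s) {
    cfg <- simulation_config(
      seed = s, n_genes = 500, n_samples = 20,
      planted_sets = list(list(name = "null", genes = set_genes,
                               delta = 0, fraction = 0.5)))
    sim <- simulate_expression(cfg)
    sc <- ssgsea_score(tmm_normalize(sim$counts)$logcpm,
                       gene_set("null", set_genes))
    lab <- sim$truth[, "null"]
    suppressWarnings(
      wilcox.test(sc[lab], sc[!lab])$p.value) < 0.01
  }, logical(1))
  expect_gte(sum(!hits), 45)
})

test_that("planted sets referencing unknown genes fail by name", {
  cfg <- simulation_config(
    seed = 1, n_genes = 10, n_samples = 4,
    planted_sets = list(list(name = "bad", genes = c("g0001", "nope"),
                             delta = 1, fraction = 0.5)))
  expect_error(simulate_expression(cfg), "nope")
})

test_that("noise-free simulated curves reproduce their generating parameters", {
  cfg <- simulation_config(
    seed = 2, noise_sd = 0,
    hill_params = list(M = c(top = 100, bottom = 0, ic50 = 0.001,
                             slope = 1)))
  sim <- simulate_dose_response(cfg, "M")
  # targeted == control when the targeted curve is the flat control curve
  cfg_flat <- simulation_config(
    seed = 2, noise_sd = 0,
    hill_params = list(M = c(top = 100, bottom = 100, ic50 = 1, slope = 1)))
  sflat <- simulate_dose_response(cfg_flat, "M")
  expect_equal(compute_nauc(sflat$targeted, sflat$control)$nauc_median, 1.0)
  # and 4PL refit recovers the generating IC50 almost exactly
  f <- fit_4pl(sim$targeted[[1]])
  expect_lt(abs(f$ic50 - 0.001) / 0.001, 1e-6)
  expect_error(simulate_dose_response(cfg, "unknown"), "unknown")
})

test_that("cohort marginals converge to their configured frequencies", {
  cfg <- simulation_config(seed = 3)
  co <- simulate_cohort(cfg, 10000)
  expect_gt(mean(co$RB1_state == "biallelic_loss"), 0.09)
  expect_lt(mean(co$RB1_state == "biallelic_loss"), 0.11)
  expect_lt(abs(mean(co$slfn11_truth) - 0.40), 0.02)
  # positive fraction recovered by the mixture caller within +/- 0.03
  cl <- call_slfn11(co$SLFN11_expr[1:5000])
  expect_lt(abs(cl$positive_fraction - 0.40), 0.03)
  # all-zero genotype frequencies give an all-wild-type funnel
  cfg0 <- simulation_config(seed = 4,
                            genotype_freqs = c(RB1 = 0, TP53 = 0, ATR = 0,
                                               CHD1 = 0))
  co0 <- simulate_cohort(cfg0, 500)
  rep0 <- run_funnel(co0, function(x) rep(FALSE, length(x)))
  expect_identical(rep0$stages$n_selected[1:3], c(0L, 0L, 0L))
})

test_that("simulated IHC cores are triplicates whose percentages sum to 100", {
  cfg <- simulation_config(seed = 6,
                           ihc_profiles = list(c(100, 0, 0, 0),
                                               c(0, 0, 0, 100),
                                               c(10, 40, 30, 20)))
  ihc <- simulate_ihc(cfg)
  expect_identical(nrow(ihc), 9L)
  expect_identical(as.integer(table(ihc$tumor_id)), rep(3L, 3))
  sums <- rowSums(ihc[, paste0("pct", 0:3)])
  expect_equal(sums, rep(100, 9))
  avg <- average_cores(ihc)
  expect_identical(avg$h_score[avg$tumor_id == "tumor01"], 0)
  expect_identical(avg$h_score[avg$tumor_id == "tumor02"], 300)
  # mixed profile: mean of the three per-core hand-computed H-scores
  mixed <- ihc[ihc$tumor_id == "tumor03", ]
  hand <- mean(apply(mixed[, paste0("pct", 0:3)], 1,
                     function(p) sum(p * 0:3)))
  expect_equal(avg$h_score[avg$tumor_id == "tumor03"], hand)
})
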