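base_ann <- function(...) {
  defaults <- list(model_id = "m", phenotype = "ARPC", b7h3_positive = TRUE,
                   RB1 = "wt", TP53 = "wt", ATR = "wt", CHD1 = "wt",
                   BRCA2 = "wt", slfn11 = FALSE, repstress_z = 0,
                   observed_response = NA_character_)
  mod <- utils::modifyList(defaults, list(...))
  as.data.frame(mod, stringsAsFactors = FALSE)
}

test_that("canonical model profiles are routed to the documented rules", {
  # SCNPC-like: RB1 null, TP53 altered, SLFN11+ -> replication-stress rule
  c1 <- classify_model(base_ann(RB1 = "biallelic_loss", TP53 = "altered",
                                slfn11 = TRUE, repstress_z = 2))
  expect_identical(c1$predicted, "responder")
  expect_identical(c1$rule_fired, "rb1_loss_or_repstress")
  # RB1-wt / SLFN11- / TP53-wt / no repair lesion -> nonresponder
  c2 <- classify_model(base_ann())
  expect_identical(c2$predicted, "nonresponder")
  expect_identical(c2$rule_fired, "tp53_wt")
  # CHD1 loss rescues an RB1-wt SLFN11- model
  c3 <- classify_model(base_ann(CHD1 = "altered"))
  expect_identical(c3$predicted, "responder")
  expect_identical(c3$rule_fired, "dna_repair_loss")
  expect_match(c3$rationale, "CHD1")
  # ATR loss likewise
  c4 <- classify_model(base_ann(ATR = "altered"))
  expect_identical(c4$rule_fired, "dna_repair_loss")
  expect_match(c4$rationale, "ATR")
  # target-antigen knockout is ineligible regardless of biomarkers
  c5 <- classify_model(base_ann(b7h3_positive = FALSE,
                                RB1 = "biallelic_loss", slfn11 = TRUE))
  expect_identical(c5$predicted, "ineligible")
  # SLFN11 alone suffices
  c6 <- classify_model(base_ann(slfn11 = TRUE, TP53 = "altered"))
  expect_identical(c6$rule_fired, "slfn11_positive")
  # TP53 altered with nothing positive is left indeterminate
  c7 <- classify_model(base_ann(TP53 = "altered"))
  expect_identical(c7$predicted, "indeterminate")
  # BRCA2 loss fires no rule: TP53-wt dominates
  c8 <- classify_model(base_ann(BRCA2 = "altered"))
  expect_identical(c8$predicted, "nonresponder")
})

test_that("classification is total, deterministic, and monotone in RB1", {
  states <- c("biallelic_loss", "altered", "monoallelic_or_wt", "wt")
  grid <- expand.grid(RB1 = states, TP53 = states, ATR = c("wt", "altered"),
                      CHD1 = c("wt", "altered"), slfn11 = c(TRUE, FALSE),
                      b7h3 = c(TRUE, FALSE), rsz = c(-1, 0, 2),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ann <- base_ann(RB1 = g$RB1, TP53 = g$TP53, ATR = g$ATR, CHD1 = g$CHD1,
                    slfn11 = g$slfn11, b7h3_positive = g$b7h3,
                    repstress_z = g$rsz)
    call1 <- classify_model(ann)
    expect_identical(nrow(call1), 1L)
    expect_true(call1$predicted %in% c("responder", "nonresponder",
                                       "ineligible", "indeterminate"))
    expect_identical(call1, classify_model(ann))  # deterministic
    # flipping RB1 to biallelic loss never downgrades a responder
    flipped <- classify_model(transform(ann, RB1 = "biallelic_loss"))
    if (call1$predicted == "responder")
      expect_identical(flipped$predicted, "responder")
  }
  expect_error(classify_model(base_ann(RB1 = NA)), "RB1")
})

test_that("rule-generated synthetic cohorts are recovered at the label-noise floor", {
  set.seed(99)
  n <- 1000
  eps <- 0.1
  states <- c("biallelic_loss", "wt")
  ann <- data.frame(
    model_id = paste0("m", 1:n),
    phenotype = "ARPC",
    b7h3_positive = TRUE,
    RB1 = sample(states, n, TRUE, prob = c(0.1, 0.9)),
    TP53 = sample(c("altered", "wt"), n, TRUE, prob = c(0.4, 0.6)),
    ATR = sample(c("altered", "wt"), n, TRUE, prob = c(0.02, 0.98)),
    CHD1 = sample(c("altered", "wt"), n, TRUE, prob = c(0.02, 0.98)),
    slfn11 = runif(n) < 0.4,
    repstress_z = rnorm(n),
    stringsAsFactors = FALSE)
  calls <- classify_models(ann)
  decided <- calls$predicted %in% c("responder", "nonresponder")
  truth <- calls$predicted[decided]
  noisy <- ifelse(runif(sum(decided)) < eps,
                  ifelse(truth == "responder", "NR", "R"),
                  ifelse(truth == "responder", "R", "NR"))
  ann$observed_response <- NA_character_
  ann$observed_response[decided] <- noisy
  ev <- evaluate_calls(calls, ann)
  expect_gte(ev$accuracy, 1 - eps - 0.02)
})

test_that("evaluation counts partition correctly and handle edge cases", {
  tab <- synthetic_model_table()
  expect_error(evaluate_calls(classify_models(rbind(tab, tab)),
                              rbind(tab, tab)), "duplicated")
  # perfect-agreement fixture: observed = predicted
  sub <- tab[tab$model_id %in% c("N01", "A03", "A12"), ]
  calls <- classify_models(sub)
  sub$observed_response <- ifelse(calls$predicted == "responder", "R", "NR")
  ev <- evaluate_calls(calls, sub)
  expect_identical(sum(ev$confusion[cbind(c("responder", "nonresponder"),
                                          c("NR", "R"))]), 0L)
  # empty eligible set: all-zero confusion, no error
  none <- sub; none$observed_response <- NA_character_
  ev0 <- evaluate_calls(classify_models(none), none)
  expect_identical(sum(ev0$confusion), 0L)
})
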