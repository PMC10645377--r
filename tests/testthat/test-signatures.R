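test_that("ssGSEA equals the brute-force running-sum oracle on random matrices", {
  set.seed(42)
  worst <- 0
  for (rep in 1:200) {
    m <- matrix(rnorm(60), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    k <- sample(2:5, 1)
    gs <- gene_set("S", sample(rownames(m), k))
    got <- ssgsea_score(m, gs, normalize = FALSE)
    expected <- vapply(seq_len(ncol(m)), function(j)
      ssgsea_oracle(setNames(m[, j], rownames(m)), gs$genes), numeric(1))
    worst <- max(worst, max(abs(got - expected)))
  }
  expect_lt(worst, 1e-12)
})

test_that("ssGSEA is rank-based: monotone transforms leave scores unchanged", {
  set.seed(8)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  gs <- gene_set("S", paste0("g", 1:5))
  expect_equal(ssgsea_score(m, gs), ssgsea_score(exp(m), gs))
})

test_that("a sample whose set genes occupy the top ranks attains the cohort maximum", {
  set.seed(3)
  m <- matrix(rnorm(100), 20, 5,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
  gs <- gene_set("S", paste0("g", 1:4))
  m[1:4, 3] <- max(m) + 1:4  # set genes at the very top of sample s3
  sc <- ssgsea_score(m, gs)
  expect_identical(names(which.max(sc)), "s3")
})

test_that("degenerate gene sets are rejected by name", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_error(ssgsea_score(m, gene_set("tiny", c("g1", "zzz"))), "tiny")
  expect_error(ssgsea_score(m, gene_set("all", paste0("g", 1:10))),
               "complement")
})

test_that("z-transform centers and scales each signature, preserving order", {
  set.seed(4)
  sets <- list(gene_set("A", paste0("g", 1:5)),
               gene_set("B", paste0("g", 6:12)))
  m <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  ss <- z_transform(ssgsea_score(m, sets))
  expect_equal(unname(rowMeans(ss$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ss$z, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_identical(order(ss$z["A", ]), order(ss$raw["A", ]))
  # two samples, sample-sd convention: z = +/- 1/sqrt(2)
  two <- ss; two$raw <- ss$raw[, 1:2]; two$z <- NULL
  z2 <- z_transform(two)$z
  expect_equal(abs(as.vector(z2)), rep(1 / sqrt(2), length(z2)))
  const <- ss; const$raw[1, ] <- 5; const$z <- NULL
  expect_error(z_transform(const), "A")
})

test_that("phenotype quadrants map AR/NE scores to the four classes", {
  expect_identical(unname(call_phenotype(2, -2)), "ARPC")
  expect_identical(unname(call_phenotype(-2, 2)), "SCNPC")
  expect_identical(unname(call_phenotype(-2, -2)), "DNPC")
  expect_identical(unname(call_phenotype(2, 2)), "amphicrine")
  expect_identical(unname(call_phenotype(c(1, -1), c(-1, 1))),
                   c("ARPC", "SCNPC"))
})

test_that("the correlation screen recovers perfect monotone association", {
  set.seed(6)
  nauc <- setNames(runif(8, 0.2, 1), paste0("m", 1:8))
  z <- rbind(anti = -nauc, noise = rnorm(8))
  colnames(z) <- names(nauc)
  res <- correlate_with_response(nauc, z)
  expect_equal(res$coefficient[res$signature == "anti"], -1)
  expect_identical(res$signature[1], "anti")
})

test_that("BH adjustment matches the hand computation and constants are excluded", {
  nauc <- setNames(c(0.2, 0.4, 0.6, 0.8, 1.0), paste0("m", 1:5))
  # engineered score rows (one constant) checked through the public screen
  z <- rbind(s1 = c(0.2, 0.4, 0.6, 0.8, 1.0),
             flat = rep(1, 5))
  colnames(z) <- names(nauc)
  res <- correlate_with_response(nauc, z)
  expect_true(is.na(res$coefficient[res$signature == "flat"]))
  expect_false(isTRUE(res$significant[res$signature == "flat"]))
  # hand BH on the toy p-vector (0.01, 0.02, 0.03, 0.04): all become 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("the correlation screen is calibrated under the null", {
  set.seed(77)
  n_models <- 20
  fracs <- vapply(1:50, function(s) {
    nauc <- setNames(runif(n_models), paste0("m", 1:n_models))
    z <- matrix(rnorm(100 * n_models), 100,
                dimnames = list(paste0("sig", 1:100), names(nauc)))
    res <- correlate_with_response(nauc, z)
    mean(res$significant)
  }, numeric(1))
  expect_lt(mean(fracs), 0.05)
})

test_that("rank-sum group comparisons give exact enumerated p and Holm adjustment", {
  # most extreme 3-vs-3 arrangement: exact two-sided p = 2 / choose(6,3) = 0.1
  res <- group_compare(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)
  # identical groups: p = 1
  res2 <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gte(res2$p_adjusted, 0.99)
  # three groups: Holm = hand computation on the 3 raw p-values
  vals <- c(1, 2, 3, 10, 11, 12, 5, 6, 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  res3 <- group_compare(vals, grp)
  hand <- {
    p <- res3$p_value
    o <- order(p)
    adj <- pmin(1, cummax((3:1) * p[o]))
    adj[order(o)]
  }
  expect_equal(res3$p_adjusted, hand)
  expect_warning(group_compare(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "c")
})
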