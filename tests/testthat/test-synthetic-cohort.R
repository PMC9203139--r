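test_that("default cohort matches the study geometry: 60 x 411 with 25 events", {
  co <- generateCohort(syntheticConfig(seed = 11))
  expect_equal(dim(co$experiment), c(411L, 60L))
  expect_equal(sum(sampleOutcome(co$experiment) == "died"), 25L)
  expect_equal(nrow(co$truth$effects), 13L)
  expect_equal(length(unique(
    SummarizedExperiment::rowData(co$experiment)$super_pathway)), 8L)
})

test_that("generation is deterministic given config and seed", {
  a <- generateCohort(syntheticConfig(seed = 5))
  b <- generateCohort(syntheticConfig(seed = 5))
  expect_identical(abundance(a$experiment), abundance(b$experiment))
  expect_identical(belowLOD(a$experiment), belowLOD(b$experiment))
  expect_identical(a$truth, b$truth)
  c <- generateCohort(syntheticConfig(seed = 6))
  expect_false(identical(abundance(a$experiment), abundance(c$experiment)))
})

test_that("raw abundances are strictly positive wherever observed", {
  co <- generateCohort(syntheticConfig(seed = 3))
  ab <- abundance(co$experiment)
  expect_true(all(ab[!is.na(ab)] > 0))
  expect_error(log10Transform(log10Transform(co$experiment)), "already")
})

test_that("null configuration has empty truth and outcome-independent columns", {
  co <- generateCohort(syntheticConfig(n_effect_metabolites = 0, seed = 21))
  expect_equal(nrow(co$truth$effects), 0L)
  # Wilcoxon screen rejects at roughly the nominal rate under the null
  pp <- preprocessCohort(co$experiment)$experiment
  uni <- univariateScreen(pp)
  rate <- mean(uni$p_value < 0.05)
  n <- nrow(uni)
  expect_gt(n, 120)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("exact event counts hold for every seed; Bernoulli mode varies", {
  for (s in 1:5) {
    co <- generateCohort(syntheticConfig(seed = s))
    expect_equal(sum(sampleOutcome(co$experiment) == "died"), 25L)
  }
  co <- generateCohort(syntheticConfig(exact_event_counts = FALSE,
                                       n_samples = 400, seed = 2))
  k <- sum(sampleOutcome(co$experiment) == "died")
  expect_true(abs(k / 400 - 0.42) < 0.1)
})

test_that("planted metabolites recover the target standardized shift at large n", {
  cfg <- syntheticConfig(n_samples = 1000, n_metabolites = 60,
                         n_effect_metabolites = 6, effect_size = 1.0,
                         lod_quantile_range = c(0, 0), seed = 31)
  co <- generateCohort(cfg)
  lg <- log10Transform(co$experiment)
  y <- sampleOutcome(lg) == "died"
  ab <- abundance(lg)
  pooled_smd <- function(v) {
    s <- sqrt(((sum(y) - 1) * var(v[y]) + (sum(!y) - 1) * var(v[!y])) /
                (length(v) - 2))
    (mean(v[y]) - mean(v[!y])) / s
  }
  smd <- vapply(co$truth$effects$metabolite_id,
                function(id) pooled_smd(ab[id, ]), numeric(1))
  expect_true(all(smd > 0.6))  # non-survivors higher for every planted one
  expect_lt(abs(mean(smd) - 1.0), 0.12)
  null_ids <- setdiff(rownames(lg), co$truth$effects$metabolite_id)
  smd0 <- vapply(null_ids, function(id) pooled_smd(ab[id, ]), numeric(1))
  expect_lt(abs(mean(smd0)), 0.1)
})

test_that("config validation rejects degenerate settings", {
  expect_error(syntheticConfig(n_effect_metabolites = 500), "exceeds")
  expect_error(syntheticConfig(within_pathway_correlation = 1), "correlation")
  expect_error(syntheticConfig(target_event_rate = 0), "event_rate")
  expect_error(syntheticConfig(lod_quantile_range = c(0, 1)), "quantile")
})

test_that("below-LOD censoring flags exactly the smallest values", {
  set.seed(44)
  vals <- matrix(10^runif(3 * 60, 4, 6), 3, 60)
  x <- tiny_experiment(vals)
  # zero quantile: nothing flagged
  x0 <- censorBelowLOD(x, 0)
  expect_equal(sum(belowLOD(x0)), 0L)
  # quantile 0.15 on 60 samples: the 9 smallest values of that metabolite
  x1 <- censorBelowLOD(x, c(0.15, 0, 0))
  expect_equal(sum(belowLOD(x1)[1, ]), 9L)
  expect_equal(sum(belowLOD(x1)), 9L)
  smallest9 <- order(vals[1, ])[1:9]
  expect_true(all(belowLOD(x1)[1, smallest9]))
  # non-censored cells unchanged
  expect_identical(abundance(x1)[2:3, ], abundance(x)[2:3, ])
  expect_identical(abundance(x1)[1, -smallest9], abundance(x)[1, -smallest9])
  # flags sit exactly where value < threshold order statistic
  lod <- sort(vals[1, ])[10]
  expect_identical(unname(belowLOD(x1)[1, ]), unname(vals[1, ] < lod))
  expect_error(censorBelowLOD(x, 1.0), "quantile")
})

test_that("outcome intercept calibration matches the closed form and target", {
  expect_equal(calibrateOutcomeIntercept(rep(0, 50), 0.5), 0, tolerance = 1e-8)
  expect_equal(calibrateOutcomeIntercept(rep(0, 50), 0.42), qlogis(0.42),
               tolerance = 1e-8)
  set.seed(9)
  eta <- rnorm(200, sd = 2)
  for (r in c(0.2, 0.42, 0.7)) {
    b <- calibrateOutcomeIntercept(eta, r)
    expect_lt(abs(mean(plogis(b + eta)) - r), 1e-8)
  }
  # monotone in the target rate
  b1 <- calibrateOutcomeIntercept(eta, 0.3)
  b2 <- calibrateOutcomeIntercept(eta, 0.6)
  expect_lt(b1, b2)
  expect_error(calibrateOutcomeIntercept(c(1, Inf), 0.5), "finite")
})
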