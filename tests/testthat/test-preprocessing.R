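test_that("drug-metabolite exclusion removes exactly the flagged rows", {
  vals <- matrix(10^runif(10 * 6, 4, 6), 10, 6)
  x <- tiny_experiment(vals, is_drug = c(rep(TRUE, 3), rep(FALSE, 7)))
  res <- excludeDrugMetabolites(x)
  expect_equal(nrow(res$experiment), 7L)
  expect_equal(res$removed, c("m01", "m02", "m03"))
  expect_identical(rownames(res$experiment), sprintf("m%02d", 4:10))
  # no flags: identity
  x2 <- tiny_experiment(vals)
  expect_equal(nrow(excludeDrugMetabolites(x2)$experiment), 10L)
  # all flagged: empty with warning
  x3 <- tiny_experiment(vals, is_drug = rep(TRUE, 10))
  expect_warning(res3 <- excludeDrugMetabolites(x3), "drug")
  expect_equal(nrow(res3$experiment), 0L)
})

test_that("below-LOD filter uses a strict > rule and only the mask", {
  set.seed(1)
  vals <- matrix(10^runif(3 * 60, 4, 6), 3, 60)
  mask <- matrix(FALSE, 3, 60)
  mask[1, 1:7] <- TRUE   # 7/60 = 11.7% -> removed
  mask[2, 1:6] <- TRUE   # 6/60 = 10.0% exactly -> retained
  vals[mask] <- NA
  x <- tiny_experiment(vals, mask)
  res <- filterBelowLOD(x, preprocessConfig(lod_exclusion_fraction = 0.10))
  expect_equal(res$removed, "m01")
  expect_identical(rownames(res$experiment), c("m02", "m03"))
  # threshold 1 keeps everything; threshold 0 drops any flagged metabolite
  expect_equal(length(filterBelowLOD(
    x, preprocessConfig(lod_exclusion_fraction = 1))$removed), 0L)
  expect_equal(filterBelowLOD(
    x, preprocessConfig(lod_exclusion_fraction = 0))$removed, c("m01", "m02"))
  # decisions depend on the mask, never on the values
  vals2 <- vals * 1000
  x2 <- tiny_experiment(vals2, mask)
  expect_equal(filterBelowLOD(x2, preprocessConfig())$removed, "m01")
})

test_that("log10 transform maps observed cells and guards its scale tag", {
  vals <- matrix(c(100, 1, 10, 1000, 10^0.5, 10^2.5), 2, 3)
  x <- tiny_experiment(vals)
  lg <- log10Transform(x)
  expect_equal(unname(abundance(lg)[1, 1]), 2)
  expect_equal(unname(abundance(lg)[2, 1]), 0)
  expect_equal(abundanceScale(lg), "log10")
  expect_error(log10Transform(lg), "already")
  # round trip within 1e-12
  expect_equal(10^abundance(lg), abundance(x), tolerance = 1e-12)
  # offending cell named in the error
  bad <- vals; bad[2, 3] <- -1
  xb <- tiny_experiment(abs(bad))
  SummarizedExperiment::assay(xb, "abundance")[2, 3] <- -1
  expect_error(log10Transform(xb), "m02.*s03")
})

test_that("imputation fills only masked cells with the per-metabolite rule", {
  vals <- matrix(c(4, 5, 6, NA,
                   1, 2, 3, 4), 2, 4, byrow = TRUE)
  mask <- matrix(FALSE, 2, 4); mask[1, 4] <- TRUE
  # log10 scale: the half-minimum convention applies on the analysis scale
  x <- tiny_experiment(vals, mask, scale = "log10")
  res <- imputeMissing(x, preprocessConfig(imputation_strategy = "half_min"))
  expect_equal(unname(abundance(res$experiment)[1, 4]), 2)  # half of min 4
  expect_equal(res$imputed_cells, 1L)
  # observed cells bit-identical
  expect_identical(abundance(res$experiment)[!mask], abundance(x)[!mask])
  # alternative strategies
  expect_equal(unname(abundance(imputeMissing(
    x, preprocessConfig(imputation_strategy = "min"))$experiment)[1, 4]), 4)
  expect_equal(unname(abundance(imputeMissing(
    x, preprocessConfig(imputation_strategy = "min_over_sqrt2"))$experiment)[1, 4]),
    4 / sqrt(2))
  # no masked cells: identity
  x2 <- tiny_experiment(matrix(1:6 * 1.0, 2, 3))
  expect_identical(abundance(imputeMissing(x2)$experiment), abundance(x2))
  # all-missing metabolite errors
  vals3 <- matrix(c(NA, NA, NA, 1, 2, 3), 2, 3, byrow = TRUE)
  mask3 <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3, byrow = TRUE)
  expect_error(imputeMissing(tiny_experiment(vals3, mask3)), "no observed")
})

test_that("fold standardization uses train-only parameters without leakage", {
  # sample-SD convention: sd(c(1, 2, 3)) = 1, so the scaled column is +-1
  sc <- standardizeFold(matrix(c(1, 2, 3), 3, 1))
  expect_equal(drop(sc$train), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(sc$scale), 1)
  # test value equal to the train mean maps to zero
  sc2 <- standardizeFold(matrix(c(1, 2, 3), 3, 1), matrix(2, 1, 1))
  expect_equal(drop(sc2$applied[[1]]), 0)
  # constant train column scaled to zeros with warning
  expect_warning(sc3 <- standardizeFold(matrix(5, 4, 1), matrix(c(5, 9), 2, 1)),
                 "zero-variance")
  expect_equal(drop(sc3$train), rep(0, 4))
  expect_equal(drop(sc3$applied[[1]])[1], 0)
  # train parameters insensitive to the held-out values
  tr <- matrix(rnorm(20), 5, 4)
  a <- standardizeFold(tr, matrix(rnorm(8), 2, 4))
  b <- standardizeFold(tr, matrix(rnorm(8) * 100, 2, 4))
  expect_identical(a$center, b$center)
  expect_identical(a$scale, b$scale)
  expect_identical(a$train, b$train)
})

test_that("the preprocessing chain keeps its stage order and audit counts", {
  co <- generateCohort(syntheticConfig(n_samples = 30, n_metabolites = 80,
                                       n_effect_metabolites = 4, seed = 17))
  res <- preprocessCohort(co$experiment)
  rep <- res$report
  expect_equal(rep$n_input_metabolites, 80L)
  expect_lte(rep$n_after_drug_exclusion, rep$n_input_metabolites)
  expect_lte(rep$n_after_lod_filter, rep$n_after_drug_exclusion)
  expect_length(intersect(rep$removed_drug, rep$removed_lod), 0)
  expect_equal(abundanceScale(res$experiment), "log10")
  expect_false(anyNA(abundance(res$experiment)))
  expect_equal(rep$imputed_cell_count, sum(belowLOD(res$experiment)))
  # re-running the chain on its own output is rejected by the scale guard
  expect_error(preprocessCohort(res$experiment), "already")
})
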