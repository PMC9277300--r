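traitFrame <- function(M) {
  colnames(M) <- traitNames()
  as.data.frame(M)
}

test_that("min-max standardization records training extremes and clamps", {
  M <- traitFrame(matrix(c(1, 3, 5), 3, 6))
  std <- fitStandardization(M)
  expect_equal(unname(std@traitMin), rep(1, 6))
  expect_equal(unname(std@traitMax), rep(5, 6))
  Z <- normalizeTraits(M, std)
  expect_true(all(Z >= 0 & Z <= 1))
  expect_warning(z7 <- normalizeTraits(rep(7, 6), std), "clamped")
  expect_equal(unname(z7[1, ]), rep(1, 6))
})

test_that("constant traits are flagged and dropped", {
  M <- traitFrame(cbind(matrix(runif(50), 10, 5), 2))
  expect_warning(std <- fitStandardization(M), "group_metric")
  expect_true(std@dropped["group_metric"])
  Z <- normalizeTraits(M, std)
  expect_true(all(Z[, "group_metric"] == 0))
})

test_that("complexity score is the floored, scaled weighted sum", {
  std <- TraitStandardization(rep(0, 6), rep(1, 6))
  cw1 <- ComplexityWeights(c(1, 0, 0, 0, 0, 0), std, fitted = TRUE)
  expect_equal(complexityScore(c(0.5, 0, 0, 0, 0, 0), cw1), 1000 * 0.55)
  cwU <- ComplexityWeights(rep(1 / 6, 6), std, fitted = TRUE)
  expect_equal(complexityScore(rep(0, 6), cwU), 50)
  expect_error(complexityScore(rep(0.5, 6), ComplexityWeights()),
               "not been fitted")
})

test_that("complexity is linear in the standardized traits", {
  std <- TraitStandardization(rep(0, 6), rep(1, 6))
  cw <- ComplexityWeights(c(0.3, 0.2, 0.1, 0.1, 0.2, 0.1), std,
                          fitted = TRUE)
  set.seed(4)
  for (i in 1:10) {
    t1 <- runif(6); t2 <- runif(6); lam <- runif(1)
    expect_equal(complexityScore(lam * t1 + (1 - lam) * t2, cw),
                 lam * complexityScore(t1, cw) +
                   (1 - lam) * complexityScore(t2, cw),
                 tolerance = 1e-10)
  }
})

test_that("optimizer recovers the informative trait", {
  ok <- vapply(1:3, function(i) {
    d <- makeTraitExperimentSet(seed = i)
    cw <- optimizeWeights(d$eggs, d$outcomes, restarts = 15, seed = i)
    cw@weights[1]
  }, numeric(1))
  expect_true(all(ok >= 0.6))
})

test_that("optimized weights dominate uniform weights and are reproducible", {
  d <- makeTraitExperimentSet(seed = 5)
  cw1 <- optimizeWeights(d$eggs, d$outcomes, restarts = 10, seed = 99)
  cw2 <- optimizeWeights(d$eggs, d$outcomes, restarts = 10, seed = 99)
  expect_identical(cw1@weights, cw2@weights)
  expect_gte(cw1@optimInfo$objective, cw1@optimInfo$objectiveUniform)
  # running best across restarts is non-decreasing
  expect_true(all(diff(cummax(cw1@optimInfo$trace)) >= -1e-12))
})

test_that("a single outcome class yields uniform weights with a failure flag", {
  d <- makeTraitExperimentSet(seed = 6)
  o <- d$outcomes
  o$outcome <- 0
  expect_warning(cw <- optimizeWeights(d$eggs, o, restarts = 5, seed = 1),
                 "one outcome class")
  expect_true(cw@optimInfo$failed)
  expect_equal(unname(cw@weights), rep(1 / 6, 6))
})

test_that("the objective ignores the unit scale of the score", {
  d <- makeTraitExperimentSet(seed = 7)
  cwA <- optimizeWeights(d$eggs, d$outcomes, restarts = 5, seed = 3,
                         scaleUnits = 1000)
  cwB <- optimizeWeights(d$eggs, d$outcomes, restarts = 5, seed = 3,
                         scaleUnits = 17)
  expect_equal(cwA@optimInfo$objective, cwB@optimInfo$objective,
               tolerance = 1e-12)
  expect_identical(cwA@weights, cwB@weights)
})

test_that("null data admit only the chance-level optimization gain", {
  # a simplex search has 5 effective free parameters, so the expected
  # null gain is about chi^2_5 / 2 (median ~2.2 log-likelihood units);
  # anything much larger would signal an objective bug
  gains <- vapply(1:20, function(i) {
    d <- makeTraitExperimentSet(nExperiments = 120, beta1 = 0,
                                seed = 50 + i)
    o <- d$outcomes
    o$outcome <- withSeed2(i, sample(o$outcome))
    cw <- suppressWarnings(optimizeWeights(d$eggs, o, restarts = 8,
                                           seed = i))
    cw@optimInfo$objective - cw@optimInfo$objectiveUniform
  }, numeric(1))
  expect_lt(median(gains), 4)
})

test_that("frozen weights generalize to held-out data from the same mechanism", {
  train <- makeTraitExperimentSet(nExperiments = 150, seed = 21)
  test <- makeTraitExperimentSet(nExperiments = 300, seed = 22)
  cw <- optimizeWeights(train$eggs, train$outcomes, restarts = 10,
                        seed = 21)
  # held-out traits can fall outside the training range and are clamped
  fit <- suppressWarnings(validateWeights(test$eggs, test$outcomes, cw))
  expect_gt(fit@coefTable$estimate[2], 0)
  expect_lt(fit@coefTable$p[2], 0.05)
})

test_that("shuffled held-out outcomes are mostly non-significant", {
  train <- makeTraitExperimentSet(nExperiments = 150, seed = 31)
  cw <- optimizeWeights(train$eggs, train$outcomes, restarts = 10,
                        seed = 31)
  test <- makeTraitExperimentSet(nExperiments = 200, seed = 32)
  pvals <- vapply(1:20, function(i) {
    o <- test$outcomes
    o$outcome <- withSeed2(100 + i, sample(o$outcome))
    suppressWarnings(validateWeights(test$eggs, o, cw))@coefTable$p[2]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("an empty held-out set is an input error", {
  d <- makeTraitExperimentSet(seed = 41)
  cw <- optimizeWeights(d$eggs, d$outcomes, restarts = 5, seed = 41)
  expect_error(validateWeights(d$eggs, d$outcomes[0, ], cw), "empty")
})
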