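simRecords <- function(n, beta0 = -1.5, beta1 = 1.2, trueK = 1, seed = 1) {
  cfg <- simulationConfig(nExperiments = n, beta0 = beta0, beta1 = beta1,
                          trueK = trueK, seed = seed)
  computePredictors(experimentRecords(makeExperimentSet(cfg)))
}

test_that("predictor construction gives ACD, RCD, HC and unit z-scores", {
  rec <- data.frame(experiment_id = c("e1", "e2", "e3"),
                    a = c(1500, 800, 800), b = c(1000, 800, 1250),
                    outcome = c(1, 0, 0))
  out <- computePredictors(rec)
  expect_equal(out$ACD, c(500, 0, 450))
  expect_equal(out$RCD, c(0.5, 0, 0.36))
  expect_equal(out$HC, c(1000, 800, 1250))
  expect_equal(mean(out$zACD), 0)
  expect_equal(sd(out$zACD), 1)
  expect_true(all(abs(out$RCD * out$b - out$ACD) < 1e-12))
  rec$b[2] <- -1
  expect_error(computePredictors(rec), "e2")
})

test_that("the generalized Weber statistic reduces to ACD and RCD", {
  expect_equal(weberExpression(1500, 1000, 0), 500)
  expect_equal(weberExpression(1500, 1000, 1), 0.5)
  expect_equal(weberExpression(2, 4, 2), 0.125)
  expect_error(weberExpression(1, 0, 1), "positive")
})

test_that("logistic fit matches an independent Newton oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X$x1 - 0.4 * X$x2))
    if (length(unique(y)) < 2) next
    fit <- logisticFit(y, X)
    ora <- newtonLogistic(X, y)
    expect_equal(fit@coefTable$estimate, ora$coef, tolerance = 1e-6)
    expect_equal(fit@coefTable$se, ora$se, tolerance = 1e-6)
    expect_equal(fit@logLik, ora$logLik, tolerance = 1e-8)
  }
})

test_that("intercept-only MLE equals the log odds of the class counts", {
  y <- c(rep(1, 19), rep(0, 100))
  fit <- logisticFit(y)
  expect_equal(fit@coefTable$estimate[1], log(19 / 100), tolerance = 1e-6)
  expect_equal(round(fit@coefTable$estimate[1], 4), -1.6607)
})

test_that("AICc carries the small-sample correction", {
  rec <- simRecords(119, seed = 8)
  fit <- logisticFit(rec$outcome, rec["zACD"])
  expect_equal(fit@aicc - fit@aic, 12 / 116, tolerance = 1e-12)
  expect_gte(fit@aicc, fit@aic)
  expect_equal(fit@bic, -2 * fit@logLik + 2 * log(119), tolerance = 1e-10)
})

test_that("degenerate logistic inputs error loudly", {
  expect_error(logisticFit(rep(1, 20)), "both outcome classes")
  y <- rep(c(0, 1), 10)
  expect_error(logisticFit(y, data.frame(x = rep(2, 20))),
               "constant predictor")
})

test_that("Nagelkerke R2 follows the rescaled Cox-Snell formula", {
  expect_equal(eggweber:::nagelkerkeR2FromLL(-10, -10, 20), 0)
  expect_equal(eggweber:::nagelkerkeR2FromLL(-10, -5, 20),
               (1 - exp(-0.5)) / (1 - exp(-1)))
  r2s <- vapply(seq(-9.5, -5, 0.5), function(ll1)
    eggweber:::nagelkerkeR2FromLL(-10, ll1, 20), numeric(1))
  expect_true(all(diff(r2s) > 0))
  expect_error(eggweber:::nagelkerkeR2FromLL(-5, -10, 20), "nesting")
})

test_that("all-subsets selection fits the eight candidate models", {
  rec <- simRecords(150, seed = 3)
  tab <- allSubsetsSelection(rec$outcome, rec[c("zACD", "zRCD", "zHC")])
  expect_equal(nrow(tab), 8)
  expect_setequal(tab$nPar, c(1, 2, 2, 2, 3, 3, 3, 4))
  # nesting: the full model's log-likelihood is the largest
  expect_equal(max(tab$logLik), tab$logLik[tab$nPar == 4])
  expect_equal(sort(tab$rankAICc), 1:8)
})

test_that("selection identifies the generating predictor", {
  winsRCD <- vapply(1:50, function(i) {
    rec <- simRecords(300, beta1 = 1.5, trueK = 1, seed = 400 + i)
    tab <- suppressWarnings(
      allSubsetsSelection(rec$outcome, rec[c("zACD", "zRCD", "zHC")]))
    tab$model[which.min(tab$rankBIC)] == "zRCD"
  }, logical(1))
  expect_gte(mean(winsRCD), 0.8)
})

test_that("pure-noise predictors leave the intercept-only model in front", {
  winsNull <- vapply(1:20, function(i) {
    rec <- simRecords(200, beta1 = 0, seed = 500 + i)
    noise <- withSeed2(i, data.frame(n1 = rnorm(200), n2 = rnorm(200)))
    tab <- suppressWarnings(allSubsetsSelection(rec$outcome, noise))
    tab$model[which.min(tab$rankBIC)] == "1"
  }, logical(1))
  expect_gt(mean(winsNull), 0.5)
})

test_that("likelihood-ratio tests follow the chi-squared mapping", {
  rec <- simRecords(150, seed = 5)
  fitA <- logisticFit(rec$outcome, rec["zACD"])
  fitB <- logisticFit(rec$outcome, rec[c("zACD", "zRCD")])
  res <- lrt(fitA, fitB)
  expect_equal(res$df, 1)
  expect_equal(res$chisq, 2 * (fitB@logLik - fitA@logLik))
  same <- lrt(fitA, fitA)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(fitB, fitA), "not nested")
})

test_that("LRT holds its nominal type-I error under the null", {
  rejections <- vapply(1:500, function(i) {
    rec <- withSeed2(700 + i, {
      n <- 200
      x1 <- rnorm(n)
      x2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(-1 + x1))
      list(y = y, X1 = data.frame(x1 = x1),
           X2 = data.frame(x1 = x1, x2 = x2))
    })
    fitN <- logisticFit(rec$y, rec$X1)
    fitF <- logisticFit(rec$y, rec$X2)
    lrt(fitN, fitF)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("the k-scan reduces exactly to the ACD and RCD models", {
  rec <- simRecords(200, seed = 6)
  scan <- suppressWarnings(kScan(rec$outcome, rec$a, rec$b))
  expect_equal(length(scan@k), 13)
  fitACD <- logisticFit(rec$outcome, rec["zACD"])
  fitRCD <- logisticFit(rec$outcome, rec["zRCD"])
  expect_identical(scan@aic[scan@k == 0], fitACD@aic)
  expect_identical(scan@aic[scan@k == 1], fitRCD@aic)
})

test_that("the scan AIC is invariant to rescaling the complexity units", {
  rec <- simRecords(150, seed = 7)
  s1 <- suppressWarnings(kScan(rec$outcome, rec$a, rec$b))
  s2 <- suppressWarnings(kScan(rec$outcome, 3.7 * rec$a, 3.7 * rec$b))
  expect_equal(s1@aic, s2@aic, tolerance = 1e-8)
})

test_that("logistic likelihood is invariant to affine predictor rescaling", {
  rec <- simRecords(120, seed = 9)
  f1 <- logisticFit(rec$outcome, data.frame(x = rec$ACD))
  f2 <- logisticFit(rec$outcome, data.frame(x = 5 * rec$ACD + 3))
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-8)
  expect_equal(f1@coefTable$estimate[2], 5 * f2@coefTable$estimate[2],
               tolerance = 1e-6)
})

test_that("polynomial minimum recovers an exact quadratic AIC curve", {
  k <- seq(-1, 2, 0.25)
  scan <- new("WeberScan", k = k, aic = (k - 0.8)^2 + 100,
              valid = rep(TRUE, 13), polyCoef = numeric(),
              kMin = NA_real_, aicMin = NA_real_, ciLow = NA_real_,
              ciHigh = NA_real_, ciOpenLow = FALSE, ciOpenHigh = FALSE)
  out <- kMinimum(scan)
  expect_equal(out@kMin, 0.8, tolerance = 1e-6)
  expect_equal(out@aicMin, 100, tolerance = 1e-6)
  expect_equal(out@ciLow, 0.8 - sqrt(2), tolerance = 1e-5)
  expect_true(out@ciOpenHigh)   # 0.8 + sqrt(2) lies beyond the grid
  expect_false(out@ciOpenLow)
})

test_that("the scan needs at least 7 valid points for the polynomial", {
  k <- seq(0, 1, 0.25)
  scan <- new("WeberScan", k = k, aic = k^2, valid = rep(TRUE, 5),
              polyCoef = numeric(), kMin = NA_real_, aicMin = NA_real_,
              ciLow = NA_real_, ciHigh = NA_real_,
              ciOpenLow = FALSE, ciOpenHigh = FALSE)
  expect_error(kMinimum(scan), "7 valid grid points")
})

test_that("hierarchical partitioning telescopes to the full-model R2", {
  rec <- simRecords(150, seed = 11)
  hp <- hierarchicalPartitioning(rec$outcome, rec[c("zACD", "zRCD")])
  expect_equal(sum(hp$increments), hp$fullR2, tolerance = 1e-10)
  hp1 <- hierarchicalPartitioning(rec$outcome, rec["zACD"])
  expect_equal(unname(hp1$percent), 100, tolerance = 1e-10)
})

test_that("equally informative independent predictors share the partition", {
  shares <- vapply(1:50, function(i) {
    dat <- withSeed2(900 + i, {
      n <- 200
      x1 <- rnorm(n); x2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 + 0.8 * x2))
      list(y = y, X = data.frame(x1 = x1, x2 = x2))
    })
    hp <- hierarchicalPartitioning(dat$y, dat$X)
    hp$percent[1]
  }, numeric(1))
  expect_gt(mean(shares), 40)
  expect_lt(mean(shares), 60)
})

test_that("generalized VIF matches the OLS closed form in the linear case", {
  set.seed(12)
  n <- 500
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  y <- x1 + x2 + rnorm(n)
  v <- vif(lm(y ~ x1 + x2))
  r <- cor(x1, x2)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  # orthogonal design
  x3 <- rnorm(n)
  v0 <- vif(lm(y ~ x1 + x3))
  expect_equal(unname(v0), rep(1 / (1 - cor(x1, x3)^2), 2),
               tolerance = 1e-10)
  expect_lt(max(abs(v0 - 1)), 0.05)
})

test_that("VIF of a logistic fit matches car's generalized computation", {
  skip_if_not_installed("car")
  rec <- simRecords(200, seed = 13)
  fit <- logisticFit(rec$outcome, rec[c("zACD", "zRCD")])
  expect_equal(unname(vif(fit)), unname(car::vif(fit@glm)),
               tolerance = 1e-8)
})

test_that("a duplicated predictor is a singular design", {
  rec <- simRecords(100, seed = 14)
  expect_error(logisticFit(rec$outcome,
                           data.frame(a = rec$zACD, b = rec$zACD)),
               "singular|aliased")
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  res <- kruskalWallis(c(1, 2, 3, 4, 5, 6),
                       rep(c("g1", "g2"), each = 3))
  expect_equal(res$H, 27 / 7, tolerance = 1e-10)
  expect_equal(round(res$H, 3), 3.857)
  expect_equal(res$df, 1)
  # two identical groups
  same <- kruskalWallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0, tolerance = 1e-12)
  # ties against the brute-force oracle
  v <- c(1, 1, 2, 2, 3, 3)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(kruskalWallis(v, g)$H, kwOracle(v, g), tolerance = 1e-10)
  expect_equal(kruskalWallis(rep(2, 6), g), list(H = 0, df = 1, p = 1))
})

test_that("one-way ICC matches the ANOVA oracle and its limits", {
  vals <- rep(c(1, 2, 3, 4), each = 3)   # identical within units
  units <- rep(1:4, each = 3)
  expect_equal(iccOneway(vals, units), 1)
  set.seed(15)
  v2 <- rnorm(40)
  u2 <- rep(1:10, each = 4)
  expect_equal(iccOneway(v2, u2), iccOracle(v2, u2), tolerance = 1e-10)
  # no between-unit signal: ICC near 0 on average
  nulls <- vapply(1:20, function(i)
    withSeed2(i, iccOneway(rnorm(120), rep(1:30, each = 4))), numeric(1))
  expect_lt(abs(mean(nulls)), 0.15)
  expect_error(iccOneway(1:5, 1:5), "replication")
})

test_that("Pearson CI follows the Fisher-z construction", {
  x <- 1:20
  expect_equal(pearsonCI(x, x)$r, 1)
  expect_equal(pearsonCI(x, -x + 3)$r, -1)
  set.seed(16)
  y <- x + rnorm(20, 0, 4)
  res <- pearsonCI(x, y)
  r <- cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(20 - 3)
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$ciLow, tanh(z - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(res$ciHigh, tanh(z + qnorm(0.975) * se), tolerance = 1e-12)
  expect_error(pearsonCI(rep(1, 10), 1:10), "zero variance")
})
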