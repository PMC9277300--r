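test_that("feature count trait is the list length", {
  expect_equal(nFeatures(makeFeatureSet(numeric(0), numeric(0))), 0)
  expect_equal(nFeatures(makeFeatureSet(1:7, 1:7)), 7)
})

test_that("feature count on a 40-spot egg stays in the expected window", {
  # the classic unsigned detector finds roughly one keypoint per marking
  # (plus a few duplicates and interstitial blobs, minus merged markings)
  unsigned <- siftParams(polarity = "both")
  counts <- vapply(1:20, function(s) {
    img <- makeEggImage(syntheticPatternParams(nSpots = 40, seed = s))
    nFeatures(detectFeatures(img, unsigned))
  }, numeric(1))
  expect_true(all(counts >= 30 & counts <= 60))
})

test_that("position dispersion follows the RMS-from-centroid definition", {
  mask <- matrix(TRUE, 20, 20)   # area 400
  expect_equal(positionDispersion(makeFeatureSet(5, 5), mask), 0)
  # two points distance d apart: (d/2)/sqrt(A)
  d <- 6
  fs <- makeFeatureSet(c(2, 2 + d), c(3, 3))
  expect_equal(positionDispersion(fs, mask), (d / 2) / sqrt(400))
  expect_equal(positionDispersion(makeFeatureSet(numeric(0), numeric(0)),
                                  mask), 0)
})

test_that("uniform spot placement disperses positions more than clustering", {
  disp <- function(clust) vapply(1:20, function(s) {
    img <- makeEggImage(syntheticPatternParams(nSpots = 50,
                                               clustering = clust,
                                               seed = 100 + s))
    positionDispersion(detectFeatures(img), img@mask)
  }, numeric(1))
  expect_gt(mean(disp(0)), mean(disp(0.85)))
})

test_that("scale dispersion is the coefficient of variation of scales", {
  expect_equal(scaleDispersion(makeFeatureSet(1:3, 1:3, scale = c(2, 2, 2))),
               0)
  fs <- makeFeatureSet(1:2, 1:2, scale = c(2, 4))
  expect_equal(scaleDispersion(fs), sd(c(2, 4)) / 3)
  expect_equal(round(scaleDispersion(fs), 4), 0.4714)
  expect_equal(scaleDispersion(makeFeatureSet(1, 1)), 0)
})

test_that("orientation dispersion is the circular variance", {
  expect_equal(orientationDispersion(rep(1.3, 5)), 0)
  expect_equal(orientationDispersion(c(0, pi / 2, pi, 3 * pi / 2)), 1)
  expect_equal(orientationDispersion(c(0, pi / 2)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(orientationDispersion(numeric(0)), 0)
})

test_that("Redies change matches the finite-difference oracle on ramps", {
  nr <- 40; nc <- 60
  mask <- matrix(TRUE, nr, nc)
  flat <- EggImage(matrix(0.5, nr, nc), mask)
  expect_equal(rediesChange(flat), 0)
  s <- 0.004
  ramp <- EggImage(matrix(rep(s * (0:(nc - 1)), each = nr), nr), mask)
  expect_equal(rediesChange(ramp), s, tolerance = 1e-12)
  # doubling the contrast doubles the trait; a constant offset changes nothing
  ramp2 <- EggImage(2 * ramp@intensity, mask)
  expect_equal(rediesChange(ramp2), 2 * s, tolerance = 1e-12)
  off <- EggImage(ramp@intensity + 0.1, mask)
  expect_equal(rediesChange(off), s, tolerance = 1e-12)
  # high-contrast period-4 checkerboard beats a smooth gradient
  chk <- EggImage(0.5 + 0.2 * outer(1:nr, 1:nc, function(i, j)
    (-1)^((i %/% 2) + (j %/% 2))), mask)
  expect_gt(rediesChange(chk), rediesChange(ramp))
})

test_that("group metric vanishes for singletons and identical descriptors", {
  # identical descriptors: V = 0
  fs <- makeFeatureSet(c(1, 2, 3), c(1, 1, 1),
                       descriptors = matrix(0.2, 3, 128))
  expect_equal(groupMetric(fs, delta = 10), 0)
  # all mutually farther than delta: T = 0
  fs2 <- makeFeatureSet(c(0, 100, 200), c(0, 0, 0),
                        descriptors = matrix(runif(3 * 128), 3))
  expect_equal(groupMetric(fs2, delta = 10), 0)
  expect_equal(groupMetric(makeFeatureSet(numeric(0), numeric(0))), 0)
})

test_that("clustered patterns score a larger group metric than uniform ones", {
  # markings small enough not to merge within clusters, sparse enough that
  # uniform placements stay mostly singletons at the 1-mm linkage cut
  gm <- function(clust) vapply(1:30, function(s) {
    img <- makeEggImage(syntheticPatternParams(nSpots = 30,
                                               spotScaleMean = 2.5,
                                               eggAxes = c(80, 55),
                                               clustering = clust,
                                               seed = 300 + s))
    groupMetric(detectFeatures(img))
  }, numeric(1))
  expect_gt(mean(gm(0.8)), mean(gm(0)))
})

test_that("side aggregation is the element-wise mean and checks identity", {
  a <- setNames(c(10, 1, 2, 0.3, 0.01, 0.5), traitNames())
  c2 <- setNames(c(20, 3, 4, 0.5, 0.03, 1.5), traitNames())
  out <- eggTraits(a, c2)
  expect_equal(unname(out["n_feat"]), 15)
  expect_equal(unname(out), (unname(a) + unname(c2)) / 2)
  expect_identical(eggTraits(a, a), setNames(unname(a), traitNames()))
  attr(a, "eggID") <- "egg1"; attr(c2, "eggID") <- "egg2"
  expect_error(eggTraits(a, c2), "different eggs")
})

test_that("linear complexity commutes with side averaging", {
  set.seed(33)
  std <- TraitStandardization(rep(0, 6), rep(1, 6))
  cw <- ComplexityWeights(runif(6), std, fitted = TRUE)
  for (i in 1:10) {
    ta <- runif(6); tc <- runif(6)
    expect_equal(complexityScore((ta + tc) / 2, cw),
                 (complexityScore(ta, cw) + complexityScore(tc, cw)) / 2,
                 tolerance = 1e-10)
  }
})

test_that("traits are invariant to a global intensity offset except contrast scaling of Redies change", {
  img <- makeEggImage(syntheticPatternParams(nSpots = 30, noiseSD = 0,
                                             backgroundIntensity = 0.45,
                                             spotContrast = 0.3, seed = 9))
  shifted <- img
  shifted@intensity[shifted@mask] <- shifted@intensity[shifted@mask] + 0.1
  t1 <- computeTraits(img)
  t2 <- computeTraits(shifted)
  expect_equal(unname(t1), unname(t2), tolerance = 1e-6)
})

test_that("position dispersion is invariant to mm-consistent rescaling", {
  img <- makeEggImage(syntheticPatternParams(nSpots = 40, noiseSD = 0,
                                             seed = 14))
  up <- rescaleToCanonical(img, 13)
  d1 <- positionDispersion(detectFeatures(img), img@mask)
  d2 <- positionDispersion(detectFeatures(up), up@mask)
  expect_equal(d1, d2, tolerance = 0.15 * d1)
})

test_that("synthetic egg sides are repeatable: within-egg ICC beats a no-signal ICC", {
  sideTrait <- function(nSpotsVec) {
    vals <- c(); unit <- c()
    for (e in seq_along(nSpotsVec)) {
      for (s in 1:4) {
        img <- makeEggImage(syntheticPatternParams(nSpots = nSpotsVec[e],
                                                   seed = 1000 * e + s))
        vals <- c(vals, nFeatures(detectFeatures(img)))
        unit <- c(unit, e)
      }
    }
    iccOneway(vals, unit)
  }
  iccSignal <- sideTrait(c(10, 30, 50, 70, 90))
  iccNull <- sideTrait(rep(40, 5))
  expect_gt(iccSignal, iccNull)
  expect_gt(iccSignal, 0.5)
})
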