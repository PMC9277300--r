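#' @import methods
#' @importFrom stats sd var coef vcov logLik AIC BIC pchisq plogis qlogis
#'   rnorm runif rbinom glm glm.fit binomial as.formula lm predict aov
#'   kruskal.test cor.test cor uniroot setNames optim quantile median
#'   cov2cor
#' @importFrom utils read.csv write.csv combn packageVersion
#' @importFrom tools md5sum
NULL

## canonical order of the six pattern-complexity traits
TRAIT_NAMES <- c("n_feat", "pos_disp", "scale_disp",
                 "orient_disp", "redies_change", "group_metric")

#' Names of the six pattern-complexity traits
#'
#' Returns the canonical names and order of the six traits: number of
#' features, positional dispersion, scale dispersion, orientation
#' dispersion, Redies change (mean intensity-gradient magnitude) and the
#' clustering-based group metric.
#'
#' @return Character vector of length 6.
#' @export
traitNames <- function() TRAIT_NAMES

# ---------------------------------------------------------------------------
# EggImage: a masked, calibrated, single-channel egg photograph
# ---------------------------------------------------------------------------

#' @rdname EggImage
#' @export
setClass("EggImage",
         slots = c(intensity = "matrix",
                   mask      = "matrix",
                   pxPerMm   = "numeric",
                   eggID     = "character",
                   side      = "character"))

setValidity("EggImage", function(object) {
  msg <- character()
  if (!all(dim(object@intensity) == dim(object@mask)))
    msg <- c(msg, "intensity and mask must have identical dimensions")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  if (!any(object@mask))
    msg <- c(msg, "mask is empty")
  rng <- range(object@intensity)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "intensity must lie in [0, 1]")
  if (any(abs(object@intensity[!object@mask]) > 1e-12))
    msg <- c(msg, "intensity outside the mask must be 0")
  if (length(object@pxPerMm) != 1 || !is.finite(object@pxPerMm) ||
      object@pxPerMm <= 0)
    msg <- c(msg, "pxPerMm must be a single positive number")
  if (!object@side %in% c("a", "b", "c", "d"))
    msg <- c(msg, "side must be one of 'a', 'b', 'c', 'd'")
  if (length(msg)) msg else TRUE
})

#' Masked single-channel egg image
#'
#' Container for one side of one egg: a single-channel intensity matrix in
#' [0, 1] (rows are y, columns are x; the coordinate origin is the top-left
#' pixel at x = 0, y = 0), a logical mask marking egg pixels, and the image
#' calibration in pixels per millimetre (the canonical working resolution is
#' 29 px/mm). Pixels outside the mask are forced to 0, emulating the
#' artificial black background the eggs are composited onto. Each egg is
#' photographed on four sides labelled a--d, with a opposite c and b
#' opposite d.
#'
#' @param intensity Numeric matrix in [0, 1] (values are clamped).
#' @param mask Logical matrix of the same dimensions; non-logical input is
#'   coerced with `> 0.5`.
#' @param pxPerMm Image scale in pixels per millimetre.
#' @param eggID Egg identifier.
#' @param side Side label, one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return An `EggImage` object.
#' @export
EggImage <- function(intensity, mask, pxPerMm = 29, eggID = "egg", side = "a") {
  if (!is.matrix(intensity)) stop("intensity must be a matrix")
  if (!is.logical(mask)) mask <- mask > 0.5
  intensity <- pmin(pmax(intensity, 0), 1)
  intensity[!mask] <- 0
  new("EggImage", intensity = intensity, mask = mask,
      pxPerMm = as.numeric(pxPerMm), eggID = eggID, side = side)
}

# ---------------------------------------------------------------------------
# PatternFeatureSet: scale-invariant local features for one egg side
# ---------------------------------------------------------------------------

#' @rdname PatternFeatureSet
#' @export
setClass("PatternFeatureSet",
         slots = c(geometry    = "data.frame",
                   descriptors = "matrix",
                   eggID       = "character",
                   side        = "character",
                   pxPerMm     = "numeric",
                   detectorParams = "list"))

setValidity("PatternFeatureSet", function(object) {
  msg <- character()
  g <- object@geometry
  need <- c("x", "y", "scale", "orientation")
  if (!all(need %in% names(g)))
    msg <- c(msg, "geometry must have columns x, y, scale, orientation")
  if (nrow(g) != nrow(object@descriptors))
    msg <- c(msg, "geometry and descriptors row counts differ")
  if (nrow(g) > 0) {
    if (any(g$scale <= 0)) msg <- c(msg, "feature scales must be positive")
    if (any(g$orientation < 0 | g$orientation >= 2 * pi + 1e-9))
      msg <- c(msg, "orientations must lie in [0, 2*pi)")
  }
  if (length(msg)) msg else TRUE
})

#' Set of local pattern features for one egg side
#'
#' Holds the keypoints extracted from a masked egg image: per-feature
#' position (0-based pixel coordinates, x = column, y = row), scale (the
#' detection sigma in pixels), principal orientation in [0, 2*pi), and a
#' fixed-length non-negative gradient-histogram descriptor (128 dimensions,
#' so position + scale + orientation + descriptor mirror the 132-dimensional
#' feature encoding used for natural pattern matching). The detector
#' parameters used are carried along for reproducibility.
#'
#' @param geometry data.frame with columns `x`, `y`, `scale`, `orientation`.
#' @param descriptors numeric matrix, one row per feature.
#' @param eggID,side,pxPerMm provenance metadata.
#' @param detectorParams list of detector settings.
#' @return A `PatternFeatureSet`.
#' @export
PatternFeatureSet <- function(geometry =
                                data.frame(x = numeric(), y = numeric(),
                                           scale = numeric(),
                                           orientation = numeric()),
                              descriptors = matrix(numeric(), nrow = 0,
                                                   ncol = 128),
                              eggID = "egg", side = "a", pxPerMm = 29,
                              detectorParams = list()) {
  new("PatternFeatureSet", geometry = geometry, descriptors = descriptors,
      eggID = eggID, side = side, pxPerMm = as.numeric(pxPerMm),
      detectorParams = detectorParams)
}

#' Number of features in a PatternFeatureSet
#' @param object A `PatternFeatureSet`.
#' @return Integer count.
#' @export
featureCount <- function(object) nrow(object@geometry)

#' Feature geometry accessor
#' @param object A `PatternFeatureSet`.
#' @return data.frame with columns x, y, scale, orientation.
#' @export
featureGeometry <- function(object) object@geometry

#' Feature descriptor accessor
#' @param object A `PatternFeatureSet`.
#' @return Numeric matrix, one row per feature.
#' @export
featureDescriptors <- function(object) object@descriptors

# ---------------------------------------------------------------------------
# TraitStandardization + ComplexityWeights
# ---------------------------------------------------------------------------

#' @rdname TraitStandardization
#' @export
setClass("TraitStandardization",
         slots = c(traitMin = "numeric", traitMax = "numeric",
                   dropped = "logical"))

setValidity("TraitStandardization", function(object) {
  if (length(object@traitMin) != 6 || length(object@traitMax) != 6 ||
      length(object@dropped) != 6)
    return("traitMin, traitMax and dropped must each have length 6")
  if (any(object@traitMax < object@traitMin))
    return("traitMax must be >= traitMin")
  TRUE
})

#' Min-max trait standardization
#'
#' Per-trait minimum and maximum over a training population, used to map
#' each trait into [0, 1] before the weighted sum. Traits that are constant
#' in the training data are flagged as dropped (their weight is forced to
#' zero downstream).
#'
#' @param traitMin,traitMax numeric(6), in [traitNames()] order.
#' @param dropped logical(6).
#' @return A `TraitStandardization`.
#' @export
TraitStandardization <- function(traitMin, traitMax,
                                 dropped = rep(FALSE, 6)) {
  new("TraitStandardization",
      traitMin = setNames(as.numeric(traitMin), TRAIT_NAMES),
      traitMax = setNames(as.numeric(traitMax), TRAIT_NAMES),
      dropped  = setNames(as.logical(dropped), TRAIT_NAMES))
}

#' @rdname ComplexityWeights
#' @export
setClass("ComplexityWeights",
         slots = c(weights         = "numeric",
                   standardization = "TraitStandardization",
                   epsilon         = "numeric",
                   scaleUnits      = "numeric",
                   fitted          = "logical",
                   optimInfo       = "list"))

setValidity("ComplexityWeights", function(object) {
  msg <- character()
  w <- object@weights
  if (length(w) != 6) msg <- c(msg, "weights must have length 6")
  if (any(w < -1e-9)) msg <- c(msg, "weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
  if (object@scaleUnits <= 0) msg <- c(msg, "scaleUnits must be positive")
  if (object@fitted) {
    s <- object@standardization
    active <- w > 1e-12 & !s@dropped
    if (any(s@traitMax[active] <= s@traitMin[active]))
      msg <- c(msg, "traitMax must exceed traitMin for every weighted trait")
  }
  if (length(msg)) msg else TRUE
})

#' Weighted-sum complexity score definition
#'
#' Bundles the six trait coefficients (constrained to the simplex:
#' non-negative and summing to one), the min-max trait standardization, a
#' positive floor `epsilon` and the unit scale of the score. The complexity
#' of a trait vector t is
#' \deqn{C = scaleUnits (\epsilon + \sum_i w_i \hat t_i)}
#' with \eqn{\hat t_i} the standardized trait clamped to [0, 1], so C is
#' strictly positive and linear in the standardized traits.
#'
#' @param weights numeric(6) on the simplex; defaults to uniform.
#' @param standardization A `TraitStandardization` (unfitted placeholder by
#'   default).
#' @param epsilon Positive floor added before scaling (default 0.05).
#' @param scaleUnits Unit scale of the score (default 1000).
#' @param fitted Whether the standardization has been fitted.
#' @param optimInfo Optimizer metadata (seed, per-restart objectives, ...).
#' @return A `ComplexityWeights`.
#' @export
ComplexityWeights <- function(weights = rep(1 / 6, 6),
                              standardization =
                                TraitStandardization(rep(0, 6), rep(1, 6)),
                              epsilon = 0.05, scaleUnits = 1000,
                              fitted = FALSE, optimInfo = list()) {
  w <- as.numeric(weights)
  w[w < 0] <- 0
  if (sum(w) <= 0) stop("at least one weight must be positive")
  w <- w / sum(w)
  new("ComplexityWeights", weights = setNames(w, TRAIT_NAMES),
      standardization = standardization, epsilon = epsilon,
      scaleUnits = scaleUnits, fitted = fitted, optimInfo = optimInfo)
}

# ---------------------------------------------------------------------------
# LogisticFit
# ---------------------------------------------------------------------------

#' @rdname logisticFit
#' @export
setClass("LogisticFit",
         slots = c(coefTable = "data.frame",
                   logLik    = "numeric",
                   aic       = "numeric",
                   aicc      = "numeric",
                   bic       = "numeric",
                   r2        = "numeric",
                   n         = "numeric",
                   nPar      = "numeric",
                   converged = "logical",
                   terms     = "character",
                   glm       = "ANY"))

# ---------------------------------------------------------------------------
# WeberScan
# ---------------------------------------------------------------------------

#' @rdname kScan
#' @export
setClass("WeberScan",
         slots = c(k        = "numeric",
                   aic      = "numeric",
                   valid    = "logical",
                   polyCoef = "numeric",
                   kMin     = "numeric",
                   aicMin   = "numeric",
                   ciLow    = "numeric",
                   ciHigh   = "numeric",
                   ciOpenLow  = "logical",
                   ciOpenHigh = "logical"))

setValidity("WeberScan", function(object) {
  if (length(object@k) != length(object@aic) ||
      length(object@k) != length(object@valid))
    return("k, aic and valid must have equal lengths")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "EggImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("EggImage '%s' side %s: %d x %d px, %.1f px/mm, mask %d px\n",
              object@eggID, object@side, d[2], d[1], object@pxPerMm,
              sum(object@mask)))
})

setMethod("show", "PatternFeatureSet", function(object) {
  cat(sprintf("PatternFeatureSet '%s' side %s: %d features, %d-d descriptors\n",
              object@eggID, object@side, featureCount(object),
              ncol(object@descriptors)))
  if (featureCount(object) > 0) {
    g <- object@geometry
    cat(sprintf("  scale range [%.2f, %.2f] px\n",
                min(g$scale), max(g$scale)))
  }
})

setMethod("show", "ComplexityWeights", function(object) {
  cat("ComplexityWeights (", if (object@fitted) "fitted" else "unfitted",
      ")\n", sep = "")
  print(round(object@weights, 4))
  cat(sprintf("  epsilon = %.3g, scaleUnits = %g\n",
              object@epsilon, object@scaleUnits))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: Rejection ~ %s  (n = %d%s)\n",
              if (length(object@terms)) paste(object@terms, collapse = " + ")
              else "1", object@n,
              if (object@converged) "" else ", NOT CONVERGED"))
  print(object@coefTable, digits = 4)
  cat(sprintf("  logLik %.3f | AIC %.3f | AICc %.3f | BIC %.3f | R2_N %.3f\n",
              object@logLik, object@aic, object@aicc, object@bic, object@r2))
})

setMethod("show", "WeberScan", function(object) {
  cat(sprintf("WeberScan: %d grid points in [%g, %g]\n",
              length(object@k), min(object@k), max(object@k)))
  if (length(object@kMin) && is.finite(object@kMin)) {
    lo <- if (object@ciOpenLow) "open" else sprintf("%.3f", object@ciLow)
    hi <- if (object@ciOpenHigh) "open" else sprintf("%.3f", object@ciHigh)
    cat(sprintf("  k_min = %.3f (AIC %.3f), +2-AIC CI: [%s, %s]\n",
                object@kMin, object@aicMin, lo, hi))
  }
})
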