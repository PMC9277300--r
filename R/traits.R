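# The six pattern-complexity traits for one egg side, and the side-a/c
# aggregation. Trait conventions: sd uses the n-1 denominator; empty
# feature sets give 0 by convention for the feature-based traits.

#' Trait (i): number of pattern features
#' @param fs A [PatternFeatureSet].
#' @return Integer count.
#' @export
nFeatures <- function(fs) featureCount(fs)

#' Trait (ii): positional dispersion of features
#'
#' Root-mean-square distance of the feature centres from their centroid,
#' divided by the square root of the mask area, so the trait is unitless
#' and invariant to mm-consistent rescaling of the image.
#'
#' @param fs A [PatternFeatureSet].
#' @param mask Logical egg mask the features were detected on.
#' @return Non-negative scalar; 0 for fewer than 2 features.
#' @export
positionDispersion <- function(fs, mask) {
  n <- featureCount(fs)
  if (n < 2) return(0)
  g <- fs@geometry
  rms <- sqrt(mean((g$x - mean(g$x))^2 + (g$y - mean(g$y))^2))
  rms / sqrt(sum(mask))
}

#' Trait (iii): scale dispersion of features
#'
#' Coefficient of variation (sd/mean, n-1 denominator) of the feature
#' scales.
#'
#' @param fs A [PatternFeatureSet].
#' @return Non-negative scalar; 0 for fewer than 2 features.
#' @export
scaleDispersion <- function(fs) {
  if (featureCount(fs) < 2) return(0)
  s <- fs@geometry$scale
  if (mean(s) == 0) return(0)
  sd(s) / mean(s)
}

#' Trait (iv): orientation dispersion of features
#'
#' Circular variance, 1 minus the length of the mean resultant vector of
#' the feature orientations; 0 when all orientations agree, 1 when they
#' cancel exactly.
#'
#' @param fs A [PatternFeatureSet] or a numeric vector of angles (radians).
#' @return Scalar in [0, 1]; 0 for an empty set.
#' @export
orientationDispersion <- function(fs) {
  th <- if (is.numeric(fs)) fs else fs@geometry$orientation
  if (length(th) == 0) return(0)
  r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  max(0, min(1, 1 - r))
}

#' Trait (v): Redies change (mean intensity-gradient magnitude)
#'
#' How much brightness changes across the egg: the mean of
#' \eqn{\sqrt{g_x^2 + g_y^2}} over mask-interior pixels, with central
#' differences, counting only pixels whose full difference stencil lies
#' inside the mask (so the artificial black background never contributes).
#'
#' @param img An [EggImage].
#' @return Mean gradient magnitude in intensity units per px; 0 (with a
#'   warning) if the mask has no interior pixel.
#' @export
rediesChange <- function(img) {
  m <- img@intensity; msk <- img@mask
  interior <- msk &
    shiftMat(msk, 1, 0, FALSE) & shiftMat(msk, -1, 0, FALSE) &
    shiftMat(msk, 0, 1, FALSE) & shiftMat(msk, 0, -1, FALSE)
  nr <- nrow(m); nc <- ncol(m)
  interior[c(1, nr), ] <- FALSE; interior[, c(1, nc)] <- FALSE
  if (!any(interior)) {
    warning("mask too small: no interior pixel for the gradient stencil")
    return(0)
  }
  gx <- (shiftMat(m, 0, -1, 0) - shiftMat(m, 0, 1, 0)) / 2
  gy <- (shiftMat(m, -1, 0, 0) - shiftMat(m, 1, 0, 0)) / 2
  mean(sqrt(gx[interior]^2 + gy[interior]^2))
}

#' Trait (vi): group metric (clustering tendency x within-cluster variation)
#'
#' Feature positions are clustered by single linkage cut at distance
#' `delta` (default the pixel equivalent of 1 mm, between the typical
#' within-cluster spacing of grouped markings and the nearest-neighbour
#' spacing of uniformly scattered ones; larger cuts let single linkage
#' chain whole patterns into one cluster).
#' Clustering tendency is `T = 1 - (n_clusters - 1)/max(1, n_features - 1)`
#' (1 = one cluster, 0 = all singletons). Within-cluster variation `V` is
#' the mean, over non-singleton clusters, of the per-cluster mean
#' standard deviation of the descriptor dimensions. The trait is `T * V`.
#'
#' @param fs A [PatternFeatureSet].
#' @param delta Single-linkage cut distance in px; defaults to the 1-mm
#'   equivalent `fs@pxPerMm`.
#' @return Non-negative scalar; 0 for an empty set, all-singleton
#'   clusterings, or identical descriptors.
#' @export
groupMetric <- function(fs, delta = fs@pxPerMm) {
  n <- featureCount(fs)
  if (n == 0) return(0)
  if (n == 1) return(0)
  g <- fs@geometry
  hc <- stats::hclust(stats::dist(cbind(g$x, g$y)), method = "single")
  cl <- stats::cutree(hc, h = delta)
  nCl <- length(unique(cl))
  tend <- 1 - (nCl - 1) / max(1, n - 1)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= 2])
  if (length(big) == 0) return(0)
  v <- vapply(big, function(k) {
    D <- fs@descriptors[cl == k, , drop = FALSE]
    mean(apply(D, 2, sd))
  }, numeric(1))
  tend * mean(v)
}

#' All six complexity traits for one egg side
#'
#' @param img An [EggImage].
#' @param fs The [PatternFeatureSet] detected on it (computed if missing).
#' @param delta Group-metric cut distance (see [groupMetric()]).
#' @param params Detector settings, used only if `fs` is missing.
#' @return Named numeric vector in [traitNames()] order, with attributes
#'   `eggID` and `side`.
#' @export
computeTraits <- function(img, fs = NULL, delta = NULL,
                          params = siftParams()) {
  if (is.null(fs)) fs <- detectFeatures(img, params)
  if (is.null(delta)) delta <- fs@pxPerMm
  tv <- c(n_feat = as.numeric(nFeatures(fs)),
          pos_disp = positionDispersion(fs, img@mask),
          scale_disp = scaleDispersion(fs),
          orient_disp = orientationDispersion(fs),
          redies_change = rediesChange(img),
          group_metric = groupMetric(fs, delta))
  stopifnot(all(is.finite(tv)), all(tv >= 0), tv["orient_disp"] <= 1)
  attr(tv, "eggID") <- img@eggID
  attr(tv, "side") <- img@side
  tv
}

#' Aggregate two non-overlapping sides into per-egg traits
#'
#' The per-egg trait vector is the element-wise mean of sides a and c
#' (opposite, non-overlapping sides), so for any linear complexity score
#' the complexity of the mean traits equals the mean of the two side
#' complexities.
#'
#' @param sideA,sideC Trait vectors from [computeTraits()].
#' @return Named numeric vector of per-egg traits.
#' @export
eggTraits <- function(sideA, sideC) {
  idA <- attr(sideA, "eggID"); idC <- attr(sideC, "eggID")
  if (!is.null(idA) && !is.null(idC) && !identical(idA, idC))
    stop("input error: sides belong to different eggs (", idA, " vs ",
         idC, ")")
  stopiffalse(length(sideA) == 6 && length(sideC) == 6,
              "trait vectors must have length 6")
  out <- setNames((as.numeric(sideA) + as.numeric(sideC)) / 2, TRAIT_NAMES)
  attr(out, "eggID") <- idA
  out
}
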