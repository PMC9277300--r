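# Feature-extraction pipeline: green-channel greyscale, two-grey-standard
# linear normalization, rescaling to the canonical 29 px/mm, and the
# scale-invariant keypoint detector.

#' Extract the green channel as the working greyscale
#'
#' Avian double cones, thought to drive achromatic pattern processing, are
#' most sensitive near the green band, so the greyscale used for pattern
#' analysis is the green channel of the calibrated RGB photograph. Values
#' are rescaled to [0, 1] if they arrive on an 8- or 16-bit integer scale.
#'
#' @param rgb A numeric array `h x w x 3` (linear values), or a matrix for
#'   an already-greyscale image (passed through with a note).
#' @return A numeric matrix in [0, 1].
#' @export
toGreenGrey <- function(rgb) {
  if (is.matrix(rgb)) {
    message("toGreenGrey: single-channel input, passed through unchanged")
    g <- rgb
  } else if (is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] >= 3) {
    g <- rgb[, , 2]
  } else {
    stop("input must be an h x w x 3 array or a matrix")
  }
  mx <- max(g)
  if (mx > 1) g <- g / if (mx <= 255) 255 else 65535
  g
}

#' Linearize an image against two grey standards
#'
#' Applies the unique linear map that sends the measured mean values of two
#' photographed grey standards to their known reflectances (0.362 and 0.198
#' for the N6.5 and N5 standards), then clamps to [0, 1]. This is the
#' two-point normalization that puts all field photographs on a common
#' linear reflectance scale.
#'
#' @param raw Numeric matrix of raw (linear) values.
#' @param meanStd1 Measured mean of the first standard (true reflectance
#'   `ref1`, default 0.362).
#' @param meanStd2 Measured mean of the second standard (true reflectance
#'   `ref2`, default 0.198).
#' @param ref1,ref2 Known standard reflectances.
#' @return Normalized matrix in [0, 1].
#' @export
normalizeGreyStandards <- function(raw, meanStd1, meanStd2,
                                   ref1 = 0.362, ref2 = 0.198) {
  if (abs(meanStd1 - meanStd2) < 1e-12)
    stop("degenerate calibration: the two grey standards are equal")
  slope <- (ref1 - ref2) / (meanStd1 - meanStd2)
  intercept <- ref1 - slope * meanStd1
  pmin(pmax(raw * slope + intercept, 0), 1)
}

#' Rescale an egg image to the canonical working resolution
#'
#' Resamples the intensity (bilinear) and the mask (nearest-neighbour) so
#' that the image is at `targetPxPerMm` (canonically 29 px/mm, the working
#' resolution all pattern metrics are computed at). An image already at the
#' target scale is returned pixel-exact.
#'
#' @param img An [EggImage].
#' @param targetPxPerMm Target resolution (default 29).
#' @return An [EggImage] at the target resolution.
#' @export
rescaleToCanonical <- function(img, targetPxPerMm = 29) {
  stopiffalse(is(img, "EggImage"), "img must be an EggImage")
  if (!is.finite(img@pxPerMm) || img@pxPerMm <= 0)
    stop("calibration error: pxPerMm unknown or non-positive")
  f <- targetPxPerMm / img@pxPerMm
  if (abs(f - 1) < 1e-12) return(img)
  nr <- max(2L, round(nrow(img@intensity) * f))
  nc <- max(2L, round(ncol(img@intensity) * f))
  intens <- asMat(EBImage::resize(img@intensity, w = nr, h = nc,
                                  filter = "bilinear"))
  mask <- asMat(EBImage::resize(matrix(as.numeric(img@mask),
                                       nrow(img@mask)),
                                w = nr, h = nc, filter = "none")) > 0.5
  EggImage(intens, mask, pxPerMm = targetPxPerMm,
           eggID = img@eggID, side = img@side)
}

#' Detect scale-invariant pattern features on a masked egg image
#'
#' Runs a difference-of-Gaussians scale-space detector on the masked
#' intensity image: extrema across space and scale are kept if they pass a
#' contrast threshold and an edge-curvature test, each keypoint is assigned
#' its dominant local gradient orientation, and a 128-dimensional
#' gradient-histogram descriptor is computed in the keypoint's rotated
#' frame. Keypoints whose centre falls outside the egg mask, or whose
#' support circle (radius = scale) crosses the mask border, are discarded so
#' the artificial black background cannot contribute edge artefacts. The
#' output is deterministic for identical input.
#'
#' @param img An [EggImage] at the canonical scale.
#' @param params Detector settings from [siftParams()].
#' @return A [PatternFeatureSet]; empty (with a warning) if the mask is
#'   empty.
#' @export
detectFeatures <- function(img, params = siftParams()) {
  stopiffalse(is(img, "EggImage"), "img must be an EggImage")
  if (!any(img@mask)) {
    warning("empty mask: no features detected")
    return(PatternFeatureSet(eggID = img@eggID, side = img@side,
                             pxPerMm = img@pxPerMm,
                             detectorParams = params))
  }
  res <- siftDetect(img@intensity, img@mask, params)
  fs <- PatternFeatureSet(geometry = res$geometry,
                          descriptors = res$descriptors,
                          eggID = img@eggID, side = img@side,
                          pxPerMm = img@pxPerMm, detectorParams = params)
  # invariant: every feature centre lies inside the mask
  if (featureCount(fs) > 0) {
    g <- fs@geometry
    inMask <- img@mask[cbind(round(g$y) + 1L, round(g$x) + 1L)]
    stopifnot(all(inMask))
  }
  fs
}

# ---------------------------------------------------------------------------
# File contracts: PNG images + sidecar JSON, feature CSVs
# ---------------------------------------------------------------------------

#' Write an egg image as PNG with mask and sidecar metadata
#'
#' Writes `<path>.png` (intensity), `<path>_mask.png` and `<path>.json`
#' (px/mm, egg id, side).
#'
#' @param img An [EggImage].
#' @param path Output path stem (without extension).
#' @return Invisibly, the paths written.
#' @export
writeEggImage <- function(img, path) {
  png::writePNG(img@intensity, paste0(path, ".png"))
  png::writePNG(matrix(as.numeric(img@mask), nrow(img@mask)),
                paste0(path, "_mask.png"))
  jsonlite::write_json(list(px_per_mm = img@pxPerMm, egg_id = img@eggID,
                            side = img@side),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(paste0(path, c(".png", "_mask.png", ".json")))
}

#' Read an egg image written by [writeEggImage()]
#' @param path Path stem (without extension).
#' @return An [EggImage].
#' @export
readEggImage <- function(path) {
  intens <- png::readPNG(paste0(path, ".png"))
  if (length(dim(intens)) == 3) intens <- intens[, , 1]
  mask <- png::readPNG(paste0(path, "_mask.png"))
  if (length(dim(mask)) == 3) mask <- mask[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  EggImage(intens, mask > 0.5, pxPerMm = meta$px_per_mm,
           eggID = meta$egg_id, side = meta$side)
}

#' Write a feature set to CSV
#'
#' Columns: `x, y, scale, orientation, d0..d127`.
#'
#' @param fs A [PatternFeatureSet].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeFeatures <- function(fs, path) {
  D <- fs@descriptors
  if (ncol(D) > 0) colnames(D) <- paste0("d", seq_len(ncol(D)) - 1L)
  df <- cbind(fs@geometry, as.data.frame(D))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [writeFeatures()]
#' @param path CSV path.
#' @param eggID,side,pxPerMm Metadata to attach.
#' @return A [PatternFeatureSet].
#' @export
readFeatures <- function(path, eggID = "egg", side = "a", pxPerMm = 29) {
  df <- read.csv(path)
  dcols <- grep("^d[0-9]+$", names(df))
  PatternFeatureSet(geometry = df[c("x", "y", "scale", "orientation")],
                    descriptors = as.matrix(df[dcols]),
                    eggID = eggID, side = side, pxPerMm = pxPerMm)
}
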