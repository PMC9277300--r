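# Scale-invariant keypoint detector and descriptor (difference-of-Gaussians
# scale space, orientation assignment from local gradients, 4x4x8 = 128-d
# gradient-histogram descriptor). Written against the classic SIFT recipe;
# matrices are indexed [row = y, col = x] with 0-based coordinates exported.

#' Detector settings for scale-invariant feature extraction
#'
#' @param contrastThreshold Minimum absolute difference-of-Gaussians response
#'   for a keypoint, on intensity scale [0, 1]. Default 0.01 (the classic
#'   0.03-on-[0,255]-equivalent weakened slightly for low-contrast natural
#'   patterns, divided by the number of scale intervals).
#' @param edgeRatio Maximum principal-curvature ratio; keypoints on edges
#'   with trace^2/det above (r+1)^2/r are discarded. Default 10, the
#'   standard literature value.
#' @param nIntervals Scale samples per octave (default 3).
#' @param sigma0 Base smoothing sigma of each octave in pixels (default 1.6).
#' @param minImageSize Smallest octave dimension processed (default 16 px).
#' @param nmsRadius Radius in px for non-maximum suppression of duplicate
#'   keypoints across adjacent scales (default 2).
#' @param polarity Which blob polarity to keep: `"dark"` (default; egg
#'   maculation is pigment darker than the ground colour, and the bright
#'   interstitial gaps between markings are not pattern elements),
#'   `"bright"`, or `"both"` for the classic unsigned detector.
#' @return A list of detector settings.
#' @export
siftParams <- function(contrastThreshold = 0.01, edgeRatio = 10,
                       nIntervals = 3, sigma0 = 1.6, minImageSize = 16,
                       nmsRadius = 2, polarity = c("dark", "bright", "both")) {
  stopiffalse(contrastThreshold > 0, "contrastThreshold must be positive")
  stopiffalse(edgeRatio >= 1, "edgeRatio must be >= 1")
  list(contrastThreshold = contrastThreshold, edgeRatio = edgeRatio,
       nIntervals = as.integer(nIntervals), sigma0 = sigma0,
       minImageSize = as.integer(minImageSize), nmsRadius = nmsRadius,
       polarity = match.arg(polarity))
}

# Gaussian pyramid for one octave: list of levels at sigma0 * 2^(i/s),
# i = 0 .. s+2, all blurred from the octave base (assumed at sigma0).
buildOctave <- function(base, p) {
  s <- p$nIntervals
  levels <- vector("list", s + 3L)
  levels[[1L]] <- base
  for (i in seq_len(s + 2L)) {
    sig <- p$sigma0 * 2^(i / s)
    inc <- sqrt(sig^2 - p$sigma0^2)
    levels[[i + 1L]] <- gblurMat(base, inc)
  }
  levels
}

# 26-neighbour extrema of the DoG stack at one interior level; a dark blob
# brightens under blurring, so dark markings are DoG maxima here
dogExtrema <- function(dPrev, dCur, dNext, thr, polarity = "both") {
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  hi <- pmax(shiftMat(dPrev, 0, 0, -Inf), shiftMat(dNext, 0, 0, -Inf))
  lo <- pmin(shiftMat(dPrev, 0, 0, Inf), shiftMat(dNext, 0, 0, Inf))
  for (sft in shifts) {
    for (d in list(dPrev, dCur, dNext)) {
      hi <- pmax(hi, shiftMat(d, sft[1], sft[2], -Inf))
      lo <- pmin(lo, shiftMat(d, sft[1], sft[2], Inf))
    }
  }
  isMax <- dCur > hi & dCur > thr
  isMin <- dCur < lo & dCur < -thr
  # exclude the one-pixel frame (incomplete neighbourhoods)
  nr <- nrow(dCur); nc <- ncol(dCur)
  isMax[c(1, nr), ] <- FALSE; isMax[, c(1, nc)] <- FALSE
  isMin[c(1, nr), ] <- FALSE; isMin[, c(1, nc)] <- FALSE
  switch(polarity, dark = isMax, bright = isMin, isMax | isMin)
}

# edge-response test on the DoG level: principal-curvature ratio
edgeKeep <- function(d, r) {
  dxx <- shiftMat(d, 0, 1, 0) + shiftMat(d, 0, -1, 0) - 2 * d
  dyy <- shiftMat(d, 1, 0, 0) + shiftMat(d, -1, 0, 0) - 2 * d
  dxy <- (shiftMat(d, 1, 1, 0) + shiftMat(d, -1, -1, 0) -
          shiftMat(d, 1, -1, 0) - shiftMat(d, -1, 1, 0)) / 4
  tr <- dxx + dyy
  det <- dxx * dyy - dxy^2
  det > 0 & tr^2 / det < (r + 1)^2 / r
}

imageGradients <- function(m) {
  gx <- (shiftMat(m, 0, -1, 0) - shiftMat(m, 0, 1, 0)) / 2
  gy <- (shiftMat(m, -1, 0, 0) - shiftMat(m, 1, 0, 0)) / 2
  nr <- nrow(m); nc <- ncol(m)
  gx[, c(1, nc)] <- 0; gy[c(1, nr), ] <- 0
  list(gx = gx, gy = gy,
       mag = sqrt(gx^2 + gy^2), ang = atan2(gy, gx) %% (2 * pi))
}

# dominant gradient orientation around (r0, c0) (1-based level coords)
assignOrientation <- function(grad, r0, c0, sigma) {
  rad <- max(3L, as.integer(round(2.5 * sigma)))
  nr <- nrow(grad$mag); nc <- ncol(grad$mag)
  rs <- max(1, r0 - rad):min(nr, r0 + rad)
  cs <- max(1, c0 - rad):min(nc, c0 + rad)
  dy <- rs - r0; dx <- cs - c0
  wR <- exp(-dy^2 / (2 * (1.5 * sigma)^2))
  wC <- exp(-dx^2 / (2 * (1.5 * sigma)^2))
  w <- outer(wR, wC) * grad$mag[rs, cs, drop = FALSE]
  ang <- grad$ang[rs, cs, drop = FALSE]
  bin <- (floor(ang / (2 * pi) * 36) %% 36) + 1
  h <- vapply(1:36, function(b) sum(w[bin == b]), numeric(1))
  if (all(h == 0)) return(0)
  # smooth the histogram once (circular) and take the peak bin centre
  hs <- (h + c(h[-1], h[1]) + c(h[36], h[-36])) / 3
  b <- which.max(hs)
  ((b - 0.5) / 36 * 2 * pi) %% (2 * pi)
}

# 128-d gradient-histogram descriptor in the keypoint's rotated frame
buildDescriptor <- function(grad, r0, c0, sigma, theta) {
  spacing <- 0.75 * sigma
  g <- seq(-7.5, 7.5, by = 1) * spacing      # 16 x 16 sample grid
  ct <- cos(theta); st <- sin(theta)
  gx <- outer(rep(1, 16), g); gy <- outer(g, rep(1, 16))
  sx <- c0 + gx * ct - gy * st               # rotate grid into image frame
  sy <- r0 + gx * st + gy * ct
  nr <- nrow(grad$mag); nc <- ncol(grad$mag)
  xf <- floor(sx); yf <- floor(sy)
  fx <- sx - xf; fy <- sy - yf
  ok <- xf >= 1 & xf < nc & yf >= 1 & yf < nr
  idx <- function(r, c) (c - 1) * nr + r
  bilin <- function(m) {
    v <- numeric(256)
    i <- which(ok)
    v[i] <- (1 - fx[i]) * (1 - fy[i]) * m[idx(yf[i], xf[i])] +
            fx[i] * (1 - fy[i]) * m[idx(yf[i], xf[i] + 1)] +
            (1 - fx[i]) * fy[i] * m[idx(yf[i] + 1, xf[i])] +
            fx[i] * fy[i] * m[idx(yf[i] + 1, xf[i] + 1)]
    v
  }
  mag <- bilin(grad$mag)
  gxv <- bilin(grad$gx); gyv <- bilin(grad$gy)
  ang <- (atan2(gyv, gxv) - theta) %% (2 * pi)
  wgt <- exp(-(as.numeric(gx)^2 + as.numeric(gy)^2) /
               (2 * (8 * spacing / 2)^2))
  sBinX <- pmin(3L, as.integer((col(gx) - 1) %/% 4))   # 4 x 4 spatial bins
  sBinY <- pmin(3L, as.integer((row(gx) - 1) %/% 4))
  oBin <- as.integer(floor(ang / (2 * pi) * 8)) %% 8L
  flat <- sBinY * 32L + as.numeric(sBinX) * 8L + oBin + 1L
  desc <- vapply(1:128, function(b) sum((mag * wgt)[flat == b]), numeric(1))
  nrm <- sqrt(sum(desc^2))
  if (nrm > 0) {
    desc <- pmin(desc / nrm, 0.2)
    desc <- desc / sqrt(sum(desc^2))
  }
  desc
}

# Full detector. Returns geometry (0-based full-resolution coords) and
# descriptors; the mask-border policy (support circle of radius = scale must
# lie inside the mask) is applied here via a distance transform.
siftDetect <- function(intensity, mask, params = siftParams()) {
  p <- params
  s <- p$nIntervals
  dmap <- asMat(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
  # the artificial black background would itself register as contrast at
  # the egg border; fill outside-mask pixels with the egg's mean intensity
  # so only the pattern generates scale-space structure
  intensity[!mask] <- mean(intensity[mask])
  # base of octave 0: assume nominal blur 0.5, bring to sigma0
  base <- gblurMat(intensity, sqrt(p$sigma0^2 - 0.25))
  octave <- 0L
  geom <- list(); descs <- list(); resp <- list()
  while (min(dim(base)) >= p$minImageSize) {
    levels <- buildOctave(base, p)
    dog <- lapply(seq_len(s + 2L), function(i) levels[[i + 1L]] - levels[[i]])
    grads <- vector("list", s + 3L)   # lazily filled per level
    for (i in 2:(s + 1L)) {
      ext <- dogExtrema(dog[[i - 1L]], dog[[i]], dog[[i + 1L]],
                        p$contrastThreshold, p$polarity %||% "both")
      keep <- ext & edgeKeep(dog[[i]], p$edgeRatio)
      if (!any(keep)) next
      rc <- which(keep, arr.ind = TRUE)
      sigLevel <- p$sigma0 * 2^((i - 1) / s)
      scaleFull <- sigLevel * 2^octave
      if (is.null(grads[[i]])) grads[[i]] <- imageGradients(levels[[i]])
      for (j in seq_len(nrow(rc))) {
        r <- rc[j, 1]; c <- rc[j, 2]
        xf <- (c - 1) * 2^octave; yf <- (r - 1) * 2^octave  # 0-based full-res
        rF <- as.integer(round(yf)) + 1L; cF <- as.integer(round(xf)) + 1L
        if (rF < 1 || rF > nrow(mask) || cF < 1 || cF > ncol(mask)) next
        if (!mask[rF, cF]) next
        if (dmap[rF, cF] <= scaleFull) next   # support circle crosses border
        theta <- assignOrientation(grads[[i]], r, c, sigLevel)
        d <- buildDescriptor(grads[[i]], r, c, sigLevel, theta)
        geom[[length(geom) + 1L]] <- c(xf, yf, scaleFull, theta)
        descs[[length(descs) + 1L]] <- d
        resp[[length(resp) + 1L]] <- abs(dog[[i]][r, c])
      }
    }
    nxt <- levels[[s + 1L]]
    base <- nxt[seq(1, nrow(nxt), by = 2), seq(1, ncol(nxt), by = 2),
                drop = FALSE]
    octave <- octave + 1L
  }
  if (!length(geom)) {
    return(list(geometry = data.frame(x = numeric(), y = numeric(),
                                      scale = numeric(),
                                      orientation = numeric()),
                descriptors = matrix(numeric(), 0, 128)))
  }
  g <- do.call(rbind, geom)
  D <- do.call(rbind, descs)
  rs <- unlist(resp)
  # non-maximum suppression: strongest response wins within a radius that
  # grows with the keypoint's scale (keeps duplicate pruning resolution-free)
  ord <- order(-rs)
  kept <- logical(length(ord))
  kx <- numeric(0); ky <- numeric(0)
  for (i in ord) {
    rad <- max(p$nmsRadius, 0.5 * g[i, 3])
    if (length(kx) == 0 ||
        min((kx - g[i, 1])^2 + (ky - g[i, 2])^2) > rad^2) {
      kept[i] <- TRUE
      kx <- c(kx, g[i, 1]); ky <- c(ky, g[i, 2])
    }
  }
  g <- g[kept, , drop = FALSE]; D <- D[kept, , drop = FALSE]
  ord2 <- order(g[, 2], g[, 1], g[, 3])
  g <- g[ord2, , drop = FALSE]; D <- D[ord2, , drop = FALSE]
  list(geometry = data.frame(x = g[, 1], y = g[, 2], scale = g[, 3],
                             orientation = g[, 4]),
       descriptors = D)
}
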