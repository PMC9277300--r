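# Synthetic spotted-egg image generator. Not a biological model of pattern
# formation: a controllable fixture whose pattern statistics (feature count,
# positional clustering, scale/orientation dispersion, intensity texture)
# can be dialled independently so every downstream stage is testable.

#' Parameters for the synthetic spotted-egg image generator
#'
#' @param nSpots Number of elliptical Gaussian spots (>= 0).
#' @param spotScaleMean Mean spot sigma in px (default 3).
#' @param spotScaleCV Coefficient of variation of spot sigma, >= 0
#'   (log-normal draws).
#' @param spotElongation Axis ratio of the spots, >= 1; the geometric mean
#'   of the two axes equals the drawn sigma.
#' @param orientationConcentration von Mises concentration of spot
#'   orientations around a random per-image mean; 0 = uniform.
#' @param clustering In [0, 1]; 0 draws spot centres uniformly inside the
#'   egg, values towards 1 use a parent--offspring (Thomas-like) process
#'   whose offspring dispersion shrinks from egg scale to spot scale.
#' @param backgroundIntensity Egg ground colour in [0, 1].
#' @param spotContrast Spot darkness relative to ground, in [0, 1].
#' @param noiseSD Gaussian pixel noise sd (intensity units).
#' @param eggAxes `c(semiMajor, semiMinor)` of the egg ellipse in px.
#' @param canvas `c(nrow, ncol)` of the image; default fits the egg with a
#'   6-px margin.
#' @param seed Integer seed; identical parameters + seed give a
#'   bit-identical image.
#' @return A list of validated generator parameters.
#' @export
syntheticPatternParams <- function(nSpots = 40, spotScaleMean = 3,
                                   spotScaleCV = 0.3, spotElongation = 1.6,
                                   orientationConcentration = 2,
                                   clustering = 0,
                                   backgroundIntensity = 0.55,
                                   spotContrast = 0.35, noiseSD = 0.02,
                                   eggAxes = c(52, 36), canvas = NULL,
                                   seed = 1) {
  stopiffalse(nSpots >= 0, "nSpots must be >= 0")
  stopiffalse(spotScaleCV >= 0, "spotScaleCV must be >= 0")
  stopiffalse(spotElongation >= 1, "spotElongation must be >= 1")
  stopiffalse(orientationConcentration >= 0,
              "orientationConcentration must be >= 0")
  stopiffalse(clustering >= 0 && clustering <= 1,
              "clustering must be in [0, 1]")
  stopiffalse(noiseSD >= 0, "noiseSD must be >= 0")
  stopiffalse(all(eggAxes > 2), "egg axes must exceed 2 px")
  if (spotScaleMean <= 0 || spotScaleMean > 2 * eggAxes[2])
    stop("parameter error: spot scale must be positive and no larger than ",
         "the egg minor axis")
  backgroundIntensity <- min(max(backgroundIntensity, 0), 1)
  spotContrast <- min(max(spotContrast, 0), 1)
  if (is.null(canvas)) canvas <- c(2 * eggAxes[2] + 12, 2 * eggAxes[1] + 12)
  stopiffalse(canvas[1] >= 2 * eggAxes[2] + 2 &&
                canvas[2] >= 2 * eggAxes[1] + 2,
              "egg axes must fit inside the canvas")
  list(nSpots = as.integer(nSpots), spotScaleMean = spotScaleMean,
       spotScaleCV = spotScaleCV, spotElongation = spotElongation,
       orientationConcentration = orientationConcentration,
       clustering = clustering,
       backgroundIntensity = backgroundIntensity,
       spotContrast = spotContrast, noiseSD = noiseSD,
       eggAxes = eggAxes, canvas = as.integer(canvas),
       seed = as.integer(seed))
}

# uniform points inside an ellipse (centre cx, cy; semi-axes a, b),
# optionally shrunk by `shrink` to keep spot supports interior
runifEllipse <- function(n, cx, cy, a, b, shrink = 0.92) {
  u <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  data.frame(x = cx + shrink * a * u * cos(phi),
             y = cy + shrink * b * u * sin(phi))
}

#' Render a synthetic spotted egg image
#'
#' Draws a filled-ellipse egg mask on a black background and renders
#' exactly `nSpots` elongated Gaussian spots inside it. Spot centres come
#' from a uniform or Thomas-like clustered point process (see
#' [syntheticPatternParams()]), spot sigmas from a log-normal with the
#' requested mean and CV, orientations from a von Mises distribution.
#' Gaussian pixel noise is added, intensities are clamped to [0, 1], and
#' pixels outside the mask are set to 0.
#'
#' @param params Parameters from [syntheticPatternParams()].
#' @param pxPerMm Calibration attached to the result. The default 6.5
#'   makes the default egg axes correspond to a realistic ~16 x 11 mm egg
#'   while keeping the canvas small; pass 29 for fixtures that must sit at
#'   the canonical working resolution.
#' @param eggID,side Metadata attached to the result.
#' @return An [EggImage].
#' @export
makeEggImage <- function(params, pxPerMm = 6.5, eggID = "synthetic",
                         side = "a") {
  p <- params
  withSeed(p$seed, {
    nr <- p$canvas[1]; nc <- p$canvas[2]
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    a <- p$eggAxes[1]; b <- p$eggAxes[2]
    xs <- matrix(rep(seq_len(nc), each = nr), nr)
    ys <- matrix(rep(seq_len(nr), nc), nr)
    mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    img <- matrix(p$backgroundIntensity, nr, nc)
    if (p$nSpots > 0) {
      if (p$clustering == 0) {
        pos <- runifEllipse(p$nSpots, cx, cy, a, b)
      } else {
        nPar <- max(1L, as.integer(round(p$nSpots / 6)))
        par <- runifEllipse(nPar, cx, cy, a, b, shrink = 0.8)
        disp <- p$spotScaleMean +
          (1 - p$clustering) * (b / 2 - p$spotScaleMean)
        pick <- sample.int(nPar, p$nSpots, replace = TRUE)
        px <- par$x[pick] + rnorm(p$nSpots, 0, disp)
        py <- par$y[pick] + rnorm(p$nSpots, 0, disp)
        # resample any centre that fell outside the (shrunk) egg
        bad <- which(((px - cx) / (0.92 * a))^2 +
                       ((py - cy) / (0.92 * b))^2 > 1)
        guard <- 0L
        while (length(bad)) {
          px[bad] <- par$x[pick[bad]] + rnorm(length(bad), 0, disp)
          py[bad] <- par$y[pick[bad]] + rnorm(length(bad), 0, disp)
          bad <- bad[((px[bad] - cx) / (0.92 * a))^2 +
                       ((py[bad] - cy) / (0.92 * b))^2 > 1]
          guard <- guard + 1L
          if (guard > 5000L) {  # fall back to uniform for stragglers
            fb <- runifEllipse(length(bad), cx, cy, a, b)
            px[bad] <- fb$x; py[bad] <- fb$y
            break
          }
        }
        pos <- data.frame(x = px, y = py)
      }
      if (p$spotScaleCV > 0) {
        sdlog <- sqrt(log(1 + p$spotScaleCV^2))
        mulog <- log(p$spotScaleMean) - sdlog^2 / 2
        sig <- pmin(exp(rnorm(p$nSpots, mulog, sdlog)), 2 * b)
      } else {
        sig <- rep(p$spotScaleMean, p$nSpots)
      }
      th <- rvonmises(p$nSpots, runif(1, 0, 2 * pi),
                      p$orientationConcentration)
      e <- sqrt(p$spotElongation)
      for (i in seq_len(p$nSpots)) {
        su <- sig[i] * e; sv <- sig[i] / e
        rad <- ceiling(3.5 * su)
        r0 <- max(1, round(pos$y[i]) - rad); r1 <- min(nr, round(pos$y[i]) + rad)
        c0 <- max(1, round(pos$x[i]) - rad); c1 <- min(nc, round(pos$x[i]) + rad)
        if (r0 > r1 || c0 > c1) next
        dx <- outer(rep(1, r1 - r0 + 1), c0:c1 - pos$x[i])
        dy <- outer(r0:r1 - pos$y[i], rep(1, c1 - c0 + 1))
        u <- dx * cos(th[i]) + dy * sin(th[i])
        v <- -dx * sin(th[i]) + dy * cos(th[i])
        g <- exp(-(u^2 / (2 * su^2) + v^2 / (2 * sv^2)))
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] - p$spotContrast * g
      }
    }
    if (p$noiseSD > 0) img <- img + rnorm(nr * nc, 0, p$noiseSD)
    img <- pmin(pmax(img, 0), 1)
    img[!mask] <- 0
    EggImage(img, mask, pxPerMm = pxPerMm, eggID = eggID, side = side)
  })
}
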