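# Independent oracles and fixture builders used across the suite.

# seeded evaluation that restores the session RNG state afterwards
withSeed2 <- function(seed, expr) withr::with_seed(seed, expr)

# Brute-force Newton-Raphson logistic regression from the score and
# Hessian written out explicitly; independent of glm's IRLS path.
newtonLogistic <- function(X, y, maxit = 100, tol = 1e-12) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  V <- solve(t(X) %*% (X * (mu * (1 - mu))))
  list(coef = as.numeric(beta), se = unname(sqrt(diag(V))),
       logLik = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# Kruskal-Wallis H from the rank formula with explicit tie correction.
kwOracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# One-way ICC from the explicit ANOVA decomposition (balanced designs).
iccOracle <- function(values, units) {
  units <- as.factor(units)
  ni <- as.numeric(table(units))
  stopifnot(length(unique(ni)) == 1)
  k <- ni[1]; a <- nlevels(units); N <- a * k
  grand <- mean(values)
  means <- tapply(values, units, mean)
  ssb <- k * sum((means - grand)^2)
  ssw <- sum((values - means[units])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Elliptical egg image with isotropic Gaussian spots at chosen centres
# (x, y are 0-based pixel coordinates); deterministic, no noise.
makeSpotImage <- function(centers, sigma = 3, nr = 84, nc = 116,
                          bg = 0.55, contrast = 0.4, pxPerMm = 29,
                          eggID = "fixture", side = "a") {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  a <- (nc - 12) / 2; b <- (nr - 12) / 2
  xs <- matrix(rep(seq_len(nc), each = nr), nr)
  ys <- matrix(rep(seq_len(nr), nc), nr)
  mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  img <- matrix(bg, nr, nc)
  if (!is.null(centers) && nrow(centers) > 0) {
    for (i in seq_len(nrow(centers))) {
      d2 <- (xs - (centers[i, 1] + 1))^2 + (ys - (centers[i, 2] + 1))^2
      img <- img - contrast * exp(-d2 / (2 * sigma^2))
    }
  }
  EggImage(img, mask, pxPerMm = pxPerMm, eggID = eggID, side = side)
}

# Minimal feature set with hand-chosen geometry/descriptors.
makeFeatureSet <- function(x, y, scale = rep(2, length(x)),
                           orientation = rep(0, length(x)),
                           descriptors = NULL, pxPerMm = 29) {
  if (is.null(descriptors))
    descriptors <- matrix(0.1, length(x), 128)
  PatternFeatureSet(geometry = data.frame(x = x, y = y, scale = scale,
                                          orientation = orientation),
                    descriptors = descriptors, pxPerMm = pxPerMm)
}

# Long-format experiment table with analytic complexities (no images).
makeLongExperiments <- function(a, b, outcome, clutchSize = 2) {
  n <- length(a)
  do.call(rbind, lapply(seq_len(n), function(i) {
    eid <- sprintf("exp%02d", i)
    data.frame(experiment_id = eid,
               clutch_id = paste0("c", i),
               role = c(rep("host", clutchSize), "experimental"),
               egg_id = c(sprintf("%s_h%d", eid, seq_len(clutchSize)),
                          paste0(eid, "_x")),
               complexity = c(rep(b[i], clutchSize), a[i]),
               outcome = outcome[i],
               species = "prinia")
  }))
}
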