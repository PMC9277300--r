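# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched. seed = NULL runs expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive child seeds from one master seed, below 2^31.
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# z-score with the n-1 sd convention; errors on constant input.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# truncated-normal draws (lower truncation only), by rejection
rtruncnorm_low <- function(n, mean, sd, min) {
  if (sd == 0) return(rep(pmax(mean, min), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < min)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < min]
    guard <- guard + 1L
    if (guard > 10000L) stop("internal error: truncated-normal rejection failed")
  }
  out
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 gives the uniform circle
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out %% (2 * pi)
}

# shift a matrix by (dr, dc), padding with `fill`
shiftMat <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Gaussian blur with the brush capped to the image size (small pyramid
# octaves would otherwise exceed EBImage's filter-size limit)
gblurMat <- function(m, sigma) {
  if (sigma < 1e-8) return(m)
  rad <- 2 * ceiling(3 * sigma) + 1
  mn <- min(dim(m))
  if (rad > mn) rad <- mn - (1 - mn %% 2)
  if (rad < 3) return(m)
  asMat(EBImage::gblur(m, sigma = sigma, radius = rad))
}

# coerce possible EBImage Image output back to a plain matrix
asMat <- function(x) {
  d <- dim(x)
  matrix(as.numeric(x), nrow = d[1], ncol = d[2])
}

stopiffalse <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
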