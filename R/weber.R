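# Statistical machinery for the proportional-processing analysis:
# predictors (ACD, RCD, HC), logistic fits with AIC/AICc/BIC and Nagelkerke
# R2, all-subsets selection, likelihood-ratio tests, the k-scan of the
# generalized Weber statistic |a - b| / b^k with a fifth-order polynomial
# minimum and +2-AIC confidence interval, hierarchical partitioning,
# generalized VIF, Kruskal-Wallis, one-way ICC and Pearson CI.

#' Generalized Weber stimulus difference
#'
#' \eqn{|a - b| / b^k}: at `k = 0` this is the absolute complexity
#' difference (ACD); at `k = 1` the relative difference ACD/b (RCD), the
#' Weber-fraction analogue. Intermediate `0 < k < 1` describes the
#' near-miss to Weber's law, `k > 1` the opposite-miss.
#'
#' @param a Experimental-egg complexity (vectorized).
#' @param b Host-clutch mean complexity, must be > 0.
#' @param k Exponent.
#' @return `|a - b| / b^k`.
#' @export
weberExpression <- function(a, b, k) {
  if (any(b <= 0)) stop("domain error: b must be positive")
  abs(a - b) / b^k
}

#' Construct the predictor set from experiment records
#'
#' Adds ACD = |a - b|, RCD = ACD/b, HC = b, and their across-experiment
#' z-scores (mean 0, sd 1 with the n-1 convention) to a record table.
#'
#' @param records data.frame with columns `a`, `b` (from
#'   [experimentRecords()]), plus `outcome`.
#' @return The records with columns `ACD`, `RCD`, `HC`, `zACD`, `zRCD`,
#'   `zHC` appended.
#' @export
computePredictors <- function(records) {
  stopiffalse(all(c("a", "b") %in% names(records)),
              "records must have columns a and b")
  bad <- which(records$b <= 0)
  if (length(bad))
    stop("data error: non-positive clutch mean b in experiment(s) ",
         paste(records$experiment_id[bad], collapse = ", "))
  records$ACD <- abs(records$a - records$b)
  records$RCD <- records$ACD / records$b
  records$HC <- records$b
  records$zACD <- zscore(records$ACD)
  records$zRCD <- zscore(records$RCD)
  records$zHC <- zscore(records$HC)
  records
}

#' Logistic regression fit with the model-selection statistic set
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `glm`), returning Wald coefficient inference and the
#' criteria used downstream: AIC = -2ll + 2p, the small-sample
#' AICc = AIC + 2p(p+1)/(n-p-1), BIC = -2ll + p log(n), and Nagelkerke's
#' R-squared against the intercept-only null.
#'
#' @param outcome 0/1 response vector.
#' @param predictors data.frame/matrix of predictors, or NULL for the
#'   intercept-only model.
#' @return A [LogisticFit]. Non-convergence or separation is flagged via
#'   the `converged` slot (with a warning), never silently.
#' @export
logisticFit <- function(outcome, predictors = NULL) {
  stopiffalse(all(outcome %in% 0:1), "outcome must be 0/1")
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  if (!is.null(predictors) && ncol(as.data.frame(predictors)) == 0)
    predictors <- NULL
  if (is.null(predictors)) {
    dat <- data.frame(.y = outcome)
    fml <- .y ~ 1
    terms <- character()
  } else {
    predictors <- as.data.frame(predictors)
    if (any(vapply(predictors, function(x) sd(x) == 0, logical(1))))
      stop("constant predictor column")
    dat <- data.frame(.y = outcome, predictors)
    terms <- names(predictors)
    fml <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (any(is.na(coef(fit))))
    stop("singular design: aliased coefficients in the logistic fit")
  ll <- as.numeric(logLik(fit))
  n <- length(outcome)
  p <- length(coef(fit))
  aic <- -2 * ll + 2 * p
  aicc <- aic + 2 * p * (p + 1) / (n - p - 1)
  bic <- -2 * ll + p * log(n)
  ll0 <- if (p == 1) ll else
    as.numeric(logLik(glm(.y ~ 1, family = binomial(), data = dat)))
  r2 <- nagelkerkeR2FromLL(ll0, ll, n)
  converged <- fit$converged && !warned && all(abs(coef(fit)) < 20)
  if (!converged)
    warning("logistic fit flagged: non-convergence or (quasi-)separation")
  new("LogisticFit",
      coefTable = data.frame(term = rownames(co), estimate = co[, 1],
                             se = co[, 2], z = co[, 3], p = co[, 4],
                             row.names = NULL),
      logLik = ll, aic = aic, aicc = aicc, bic = bic, r2 = r2,
      n = n, nPar = p, converged = converged, terms = terms, glm = fit)
}

# Nagelkerke R2 from two log-likelihoods
nagelkerkeR2FromLL <- function(ll0, ll1, n) {
  if (ll1 < ll0 - 1e-8)
    stop("invalid nesting: full-model log-likelihood below the null's")
  ll1 <- max(ll1, ll0)
  r2cs <- 1 - exp(2 * (ll0 - ll1) / n)
  denom <- 1 - exp(2 * ll0 / n)
  if (denom <= 0) return(0)
  r2cs / denom
}

#' Nagelkerke's R-squared
#'
#' Cox--Snell R2 rescaled to a [0, 1] range:
#' \eqn{R^2_N = (1 - e^{2(ll_0 - ll_1)/n}) / (1 - e^{2 ll_0 / n})}.
#'
#' @param fit Full-model [LogisticFit].
#' @param nullFit Intercept-only [LogisticFit] on the same data.
#' @return Scalar in [0, 1].
#' @export
nagelkerkeR2 <- function(fit, nullFit) {
  stopiffalse(fit@n == nullFit@n, "fits must use the same data")
  nagelkerkeR2FromLL(nullFit@logLik, fit@logLik, fit@n)
}

#' All-subsets logistic model selection over up to four predictors
#'
#' Fits every predictor subset (including the intercept-only model) and
#' ranks the models by AICc and by BIC.
#'
#' @param outcome 0/1 response.
#' @param predictors data.frame of (z-scored) predictors, typically
#'   `zACD`, `zRCD`, `zHC`.
#' @return data.frame with one row per model: `model`, `nPar`, `logLik`,
#'   `AIC`, `AICc`, `BIC`, `deltaAICc`, `rankAICc`, `rankBIC`, `failed`.
#'   Fit failures are marked per model, not dropped silently.
#' @export
allSubsetsSelection <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  nm <- names(predictors)
  stopiffalse(length(nm) >= 1 && length(nm) <= 4,
              "between 1 and 4 predictors supported")
  subsets <- c(list(character()),
               unlist(lapply(seq_along(nm), function(k)
                 combn(nm, k, simplify = FALSE)), recursive = FALSE))
  rows <- lapply(subsets, function(s) {
    lab <- if (length(s)) paste(s, collapse = " + ") else "1"
    fit <- tryCatch(
      logisticFit(outcome,
                  if (length(s)) predictors[s] else NULL),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(model = lab, nPar = length(s) + 1,
                        logLik = NA_real_, AIC = NA_real_, AICc = NA_real_,
                        BIC = NA_real_, failed = TRUE))
    data.frame(model = lab, nPar = fit@nPar, logLik = fit@logLik,
               AIC = fit@aic, AICc = fit@aicc, BIC = fit@bic,
               failed = !fit@converged)
  })
  out <- do.call(rbind, rows)
  out$deltaAICc <- out$AICc - min(out$AICc, na.rm = TRUE)
  out$rankAICc <- rank(out$AICc, na.last = "keep")
  out$rankBIC <- rank(out$BIC, na.last = "keep")
  out[order(out$AICc), ]
}

#' Likelihood-ratio test between nested logistic fits
#'
#' \eqn{\chi^2 = 2(ll_{full} - ll_{nested})} with df the difference in
#' parameter counts and the p-value from the upper chi-squared tail.
#'
#' @param nested,full [LogisticFit] objects on the same data, with the
#'   nested model's terms a subset of the full model's.
#' @return list with `chisq`, `df`, `p`.
#' @export
lrt <- function(nested, full) {
  stopiffalse(nested@n == full@n, "fits must use the same data")
  if (!all(nested@terms %in% full@terms))
    stop("models are not nested")
  df <- full@nPar - nested@nPar
  chisq <- max(0, 2 * (full@logLik - nested@logLik))
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Scan the Weber exponent k against model AIC
#'
#' For each k on the grid, the generalized Weber statistic
#' `|a - b| / b^k` is z-scored across experiments and used as the single
#' predictor of rejection; the model's AIC is recorded. By construction
#' the scan reduces exactly to the ACD model at k = 0 and the RCD model at
#' k = 1 (z-scoring leaves the AIC unchanged under the affine predictor
#' transformations involved).
#'
#' @param outcome 0/1 response.
#' @param a,b Experimental-egg and clutch-mean complexities (b > 0).
#' @param kGrid Exponent grid, default `seq(-1, 2, by = 0.25)` (13 points).
#' @return A [WeberScan] with the grid AICs (minimum not yet estimated;
#'   see [kMinimum()]). Failed fits are flagged in `valid` with a warning
#'   and excluded from the polynomial stage.
#' @export
kScan <- function(outcome, a, b, kGrid = seq(-1, 2, by = 0.25)) {
  if (any(b <= 0)) stop("domain error: b must be positive")
  aic <- rep(NA_real_, length(kGrid))
  valid <- logical(length(kGrid))
  for (i in seq_along(kGrid)) {
    w <- weberExpression(a, b, kGrid[i])
    fit <- tryCatch(logisticFit(outcome, data.frame(W = zscore(w))),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      aic[i] <- fit@aic
      valid[i] <- TRUE
    }
  }
  if (!all(valid))
    warning("k-scan: ", sum(!valid),
            " grid fit(s) failed and are excluded from the polynomial")
  new("WeberScan", k = kGrid, aic = aic, valid = valid,
      polyCoef = numeric(), kMin = NA_real_, aicMin = NA_real_,
      ciLow = NA_real_, ciHigh = NA_real_,
      ciOpenLow = FALSE, ciOpenHigh = FALSE)
}

evalPoly <- function(coefs, x) {
  out <- 0
  for (j in rev(seq_along(coefs))) out <- out * x + coefs[j]
  out
}

#' Estimate the AIC-minimizing k and its +2-AIC confidence interval
#'
#' Fits a fifth-order least-squares polynomial to the (k, AIC) points of a
#' scan; `kMin` is the real root of the polynomial's derivative inside the
#' scanned range with the smallest polynomial value (an endpoint if no
#' interior root exists). The confidence bounds are the crossings of the
#' polynomial with `AIC_min + 2` nearest `kMin` on each side, located by
#' bisection to 1e-6; a crossing that falls outside the scanned range is
#' reported as open-ended rather than extrapolated.
#'
#' @param scan A [WeberScan] from [kScan()] with >= 7 valid grid points.
#' @return The scan with `polyCoef`, `kMin`, `aicMin`, `ciLow`, `ciHigh`,
#'   `ciOpenLow`, `ciOpenHigh` filled in.
#' @export
kMinimum <- function(scan) {
  ok <- scan@valid & is.finite(scan@aic)
  if (sum(ok) == 0) stop("scan error: all grid fits failed")
  stopiffalse(sum(ok) >= 7, "need at least 7 valid grid points")
  k <- scan@k[ok]; aic <- scan@aic[ok]
  # least squares on the (possibly overdetermined) Vandermonde basis
  X <- outer(k, 0:5, `^`)
  cf <- as.numeric(qr.coef(qr(X), aic))
  lo <- min(k); hi <- max(k)
  dcf <- cf[-1] * (1:5)
  roots <- polyroot(dcf)
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  real <- real[real >= lo & real <= hi]
  cand <- unique(c(real, lo, hi))
  vals <- evalPoly(cf, cand)
  interior <- cand > lo & cand < hi
  if (any(interior) && length(real)) {
    iBest <- which(interior)[which.min(vals[interior])]
    # an interior stationary point only counts if it is the global min
    if (vals[iBest] > min(vals) + 1e-12) iBest <- which.min(vals)
  } else {
    iBest <- which.min(vals)
  }
  kMin <- cand[iBest]; aicMin <- vals[iBest]
  target <- aicMin + 2
  f <- function(x) evalPoly(cf, x) - target
  findCrossing <- function(from, to) {
    # nearest sign change to `from`, scanning towards `to`
    xs <- seq(from, to, length.out = 2001)
    fv <- f(xs)
    sgn <- which(fv[-1] * fv[-length(fv)] <= 0 & is.finite(fv[-1]))
    if (!length(sgn)) return(NA_real_)
    i <- sgn[1]
    uniroot(f, c(min(xs[i], xs[i + 1]), max(xs[i], xs[i + 1])),
            tol = 1e-6)$root
  }
  ciLow <- if (kMin > lo) findCrossing(kMin, lo) else NA_real_
  ciHigh <- if (kMin < hi) findCrossing(kMin, hi) else NA_real_
  new("WeberScan", k = scan@k, aic = scan@aic, valid = scan@valid,
      polyCoef = cf, kMin = kMin, aicMin = aicMin,
      ciLow = ciLow, ciHigh = ciHigh,
      ciOpenLow = is.na(ciLow), ciOpenHigh = is.na(ciHigh))
}

#' Full Weber-exponent scan: grid, fits, polynomial minimum and CI
#'
#' Convenience wrapper running [kScan()] then [kMinimum()].
#'
#' @inheritParams kScan
#' @return A completed [WeberScan].
#' @export
weberScan <- function(outcome, a, b, kGrid = seq(-1, 2, by = 0.25)) {
  kMinimum(kScan(outcome, a, b, kGrid))
}

#' Hierarchical partitioning of Nagelkerke R-squared
#'
#' Averages, over all orderings of the predictors, each predictor's
#' increment to Nagelkerke's R2 when added to the model. The increments
#' telescope, so they sum exactly to the full-model R2.
#'
#' @param outcome 0/1 response.
#' @param predictors data.frame of at most 4 predictors.
#' @return list with `increments` (named, summing to the full R2),
#'   `percent` (shares of the full-model R2) and `fullR2`.
#' @export
hierarchicalPartitioning <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  nm <- names(predictors)
  stopiffalse(length(nm) >= 1 && length(nm) <= 4,
              "at most 4 predictors (exhaustive orderings)")
  n <- length(outcome)
  ll <- new.env()
  llOf <- function(s) {
    key <- paste0("m_", paste(sort(s), collapse = "|"))
    if (!is.null(ll[[key]])) return(ll[[key]])
    fit <- logisticFit(outcome, if (length(s)) predictors[s] else NULL)
    ll[[key]] <- fit@logLik
    ll[[key]]
  }
  ll0 <- llOf(character())
  r2Of <- function(s) nagelkerkeR2FromLL(ll0, llOf(s), n)
  perms <- permutations(nm)
  inc <- setNames(rep(0, length(nm)), nm)
  for (p in perms) {
    sofar <- character()
    for (v in p) {
      inc[v] <- inc[v] + (r2Of(c(sofar, v)) - r2Of(sofar))
      sofar <- c(sofar, v)
    }
  }
  inc <- inc / length(perms)
  full <- r2Of(nm)
  list(increments = inc, percent = 100 * inc / full, fullR2 = full)
}

permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' Generalized variance inflation factors
#'
#' Model-based VIFs computed from the correlation matrix of the fitted
#' coefficient covariance (intercept excluded):
#' \eqn{VIF_j = \det(R_{-j}) / \det(R)} for single-column terms, the
#' generalized definition otherwise. For an ordinary linear model with two
#' centred predictors this reduces to the classical \eqn{1/(1-r^2)}.
#'
#' @param fit A [LogisticFit] or an `lm`/`glm` with >= 2 predictors.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(fit) {
  V <- if (is(fit, "LogisticFit")) vcov(fit@glm) else vcov(fit)
  keep <- rownames(V) != "(Intercept)"
  V <- V[keep, keep, drop = FALSE]
  stopiffalse(nrow(V) >= 2, "need at least 2 predictors")
  if (any(!is.finite(V))) stop("singular design: unstable covariance")
  R <- cov2cor(V)
  dR <- det(R)
  if (!is.finite(dR) || abs(dR) < 1e-12)
    stop("singular design: predictor covariance is degenerate")
  out <- vapply(seq_len(nrow(R)), function(j)
    det(R[-j, -j, drop = FALSE]) / dR, numeric(1))
  setNames(out, rownames(R))
}

#' Kruskal--Wallis rank test
#'
#' Tie-corrected rank-based H statistic with df = groups - 1 and the
#' chi-squared upper-tail p-value (via `stats::kruskal.test`). The
#' degenerate all-values-identical case returns H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return list with `H`, `df`, `p`.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopiffalse(nlevels(groups) >= 2, "need at least 2 groups")
  stopiffalse(all(table(groups) >= 1), "every group needs >= 1 value")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = as.numeric(kt$statistic), df = as.numeric(kt$parameter),
       p = kt$p.value)
}

#' One-way random-effects intraclass correlation
#'
#' Repeatability of a measure across replicates within units (egg sides
#' within an egg, eggs within a clutch):
#' \eqn{ICC = (MS_B - MS_W) / (MS_B + (k_0 - 1) MS_W)} with mean squares
#' from the one-way ANOVA and \eqn{k_0} the unbalanced-design adjusted
#' replicates per unit, \eqn{k_0 = (N - \sum n_i^2 / N) / (a - 1)}.
#'
#' @param values Numeric vector of measurements.
#' @param units Unit labels, same length.
#' @return Scalar ICC.
#' @export
iccOneway <- function(values, units) {
  units <- as.factor(units)
  a <- nlevels(units)
  stopiffalse(a >= 2, "need at least 2 units")
  ni <- as.numeric(table(units))
  if (!any(ni >= 2)) stop("no within-unit replication")
  N <- length(values)
  fit <- aov(values ~ units)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors, length >= 4.
#' @param conf Confidence level (default 0.95).
#' @return list with `r`, `ciLow`, `ciHigh`, `n`.
#' @export
pearsonCI <- function(x, y, conf = 0.95) {
  stopiffalse(length(x) == length(y) && length(x) >= 4,
              "need paired vectors of length >= 4")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15)
    return(list(r = r, ciLow = r, ciHigh = r, n = length(x)))
  ct <- cor.test(x, y, conf.level = conf)
  list(r = as.numeric(ct$estimate), ciLow = ct$conf.int[1],
       ciHigh = ct$conf.int[2], n = length(x))
}
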