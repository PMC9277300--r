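# Weighted-sum complexity score and coefficient optimization: the six trait
# coefficients are chosen so that the absolute complexity difference between
# the experimental egg and the host clutch best predicts rejection
# (logistic log-likelihood objective, simplex-constrained weights).

#' Fit the min-max trait standardization
#'
#' Records the per-trait minimum and maximum over a training trait table.
#' Traits that are constant in the training data are flagged as dropped and
#' receive zero weight downstream.
#'
#' @param traits data.frame or matrix with the six trait columns (in
#'   [traitNames()] order or named accordingly).
#' @return A [TraitStandardization].
#' @export
fitStandardization <- function(traits) {
  M <- traitMatrix(traits)
  stopiffalse(nrow(M) >= 2, "need at least 2 rows to fit a standardization")
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  dropped <- hi - lo < 1e-12
  if (any(dropped))
    warning("constant trait(s) flagged and dropped: ",
            paste(TRAIT_NAMES[dropped], collapse = ", "))
  TraitStandardization(lo, hi, dropped)
}

# coerce a trait table/vector to an n x 6 matrix in canonical column order
traitMatrix <- function(traits) {
  if (is.numeric(traits) && is.null(dim(traits))) {
    stopiffalse(length(traits) == 6, "trait vector must have length 6")
    M <- matrix(as.numeric(traits), 1, 6, dimnames = list(NULL, TRAIT_NAMES))
    return(M)
  }
  traits <- as.data.frame(traits)
  if (all(TRAIT_NAMES %in% names(traits))) traits <- traits[TRAIT_NAMES]
  else stopiffalse(ncol(traits) == 6,
                   "trait table must have the six trait columns")
  M <- as.matrix(traits)
  colnames(M) <- TRAIT_NAMES
  M
}

#' Standardize traits to [0, 1]
#'
#' Applies the fitted min-max map; out-of-range future values are clamped
#' to [0, 1] with a warning, and dropped (constant-in-training) traits map
#' to 0.
#'
#' @param traits Trait vector, matrix or data.frame.
#' @param std A [TraitStandardization].
#' @return Matrix of standardized traits in [0, 1].
#' @export
normalizeTraits <- function(traits, std) {
  M <- traitMatrix(traits)
  rng <- std@traitMax - std@traitMin
  rng[std@dropped] <- 1
  Z <- sweep(sweep(M, 2, std@traitMin), 2, rng, "/")
  Z[, std@dropped] <- 0
  if (any(Z < -1e-9 | Z > 1 + 1e-9))
    warning("trait value(s) outside the training range were clamped")
  pmin(pmax(Z, 0), 1)
}

#' Complexity score of one or more trait vectors
#'
#' \eqn{C = scaleUnits (\epsilon + \sum_i w_i \hat t_i)} with standardized
#' traits \eqn{\hat t_i \in [0,1]}: strictly positive, linear in the
#' standardized traits (so the score of a mean trait vector equals the mean
#' of the scores), with a linear axis of magnitude.
#'
#' @param traits Trait vector, matrix or data.frame.
#' @param cw A fitted [ComplexityWeights].
#' @return Numeric vector of complexity scores (> 0).
#' @export
complexityScore <- function(traits, cw) {
  stopiffalse(is(cw, "ComplexityWeights"), "cw must be ComplexityWeights")
  if (!cw@fitted)
    stop("state error: standardization has not been fitted")
  Z <- normalizeTraits(traits, cw@standardization)
  as.numeric(cw@scaleUnits * (cw@epsilon + Z %*% cw@weights))
}

# absolute complexity difference per experiment for a weight vector w,
# given pre-standardized egg traits split by role
acdFromWeights <- function(w, expZ, hostMeanZ, scaleUnits = 1) {
  scaleUnits * abs(as.numeric((expZ - hostMeanZ) %*% w))
}

# log-likelihood of Rejection ~ z(ACD) for a simplex weight vector
weightObjective <- function(w, expZ, hostMeanZ, outcome) {
  acd <- acdFromWeights(w, expZ, hostMeanZ)
  s <- sd(acd)
  if (!is.finite(s) || s == 0) return(-Inf)
  z <- (acd - mean(acd)) / s
  fit <- tryCatch(
    glm.fit(cbind(1, z), outcome, family = binomial()),
    error = function(e) NULL, warning = function(w2) NULL)
  if (is.null(fit) || !fit$converged) {
    fit <- tryCatch(
      suppressWarnings(glm.fit(cbind(1, z), outcome, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit)) return(-Inf)
  }
  -fit$deviance / 2
}

softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}

#' Optimize the six trait coefficients to predict rejection
#'
#' Maximizes the log-likelihood of the logistic regression
#' `Rejection ~ z(ACD)`, where `ACD = |C_experimental - mean C_host|`, over
#' weight vectors on the simplex (non-negative, summing to one). The
#' search is multi-start Nelder--Mead on a softmax reparametrization of the
#' simplex; the uniform-weight vector is always included as the first
#' start, so the returned objective can never fall below the uniform
#' baseline.
#'
#' @param eggs Per-egg trait table: columns `experiment_id`, `role`
#'   (`host`/`experimental`) and the six traits.
#' @param outcomes data.frame `experiment_id`, `outcome` (0/1).
#' @param restarts Number of optimizer starts (default 50).
#' @param tol Convergence tolerance on the objective (default 1e-6).
#' @param seed Master seed for the restart draws.
#' @param epsilon,scaleUnits Score floor and unit scale (see
#'   [ComplexityWeights()]).
#' @return A fitted [ComplexityWeights]; `optimInfo` holds the per-restart
#'   objectives, the best objective, the uniform-weights objective, the
#'   seed, and a `failed` flag (TRUE with uniform weights if only one
#'   outcome class is present).
#' @export
optimizeWeights <- function(eggs, outcomes, restarts = 50, tol = 1e-6,
                            seed = 1, epsilon = 0.05, scaleUnits = 1000) {
  stopiffalse(nrow(outcomes) >= 20, "need at least 20 experiments")
  std <- fitStandardization(eggs[TRAIT_NAMES])
  Z <- normalizeTraits(eggs[TRAIT_NAMES], std)
  ids <- outcomes$experiment_id
  expZ <- matrix(NA_real_, length(ids), 6)
  hostMeanZ <- matrix(NA_real_, length(ids), 6)
  for (i in seq_along(ids)) {
    rows <- eggs$experiment_id == ids[i]
    expZ[i, ] <- Z[rows & eggs$role == "experimental", , drop = FALSE][1, ]
    hostMeanZ[i, ] <- colMeans(Z[rows & eggs$role == "host", , drop = FALSE])
  }
  y <- outcomes$outcome
  uniform <- rep(1 / 6, 6)
  if (length(unique(y)) < 2) {
    warning("flat objective: only one outcome class present; ",
            "returning uniform weights")
    return(ComplexityWeights(uniform, std, epsilon, scaleUnits,
                             fitted = TRUE,
                             optimInfo = list(failed = TRUE, seed = seed)))
  }
  objUniform <- weightObjective(uniform, expZ, hostMeanZ, y)
  starts <- withSeed(seed, c(list(rep(0, 6)), lapply(
    seq_len(max(0, restarts - 1)), function(i) rnorm(6, 0, 1.5))))
  trace <- numeric(length(starts))
  best <- list(obj = -Inf, w = uniform)
  for (i in seq_along(starts)) {
    res <- tryCatch(
      optim(starts[[i]],
            function(th) -weightObjective(softmax(th), expZ, hostMeanZ, y),
            method = "Nelder-Mead",
            control = list(reltol = tol, maxit = 800)),
      error = function(e) NULL)
    if (is.null(res)) { trace[i] <- -Inf; next }
    trace[i] <- -res$value
    if (trace[i] > best$obj) best <- list(obj = trace[i],
                                          w = softmax(res$par))
  }
  if (best$obj < objUniform) best <- list(obj = objUniform, w = uniform)
  ComplexityWeights(best$w, std, epsilon, scaleUnits, fitted = TRUE,
                    optimInfo = list(objective = best$obj,
                                     objectiveUniform = objUniform,
                                     trace = trace, seed = seed,
                                     restarts = length(starts),
                                     tol = tol, failed = FALSE))
}

#' Validate frozen complexity weights on held-out experiments
#'
#' Computes ACD on a held-out experiment set with frozen weights and
#' standardization, and fits `Rejection ~ z(ACD)`.
#'
#' @param eggs,outcomes Held-out per-egg trait table and outcomes (same
#'   format as [optimizeWeights()]).
#' @param cw Frozen, fitted [ComplexityWeights].
#' @return A [LogisticFit] for the held-out logistic regression.
#' @export
validateWeights <- function(eggs, outcomes, cw) {
  stopiffalse(nrow(outcomes) >= 1, "input error: empty held-out set")
  stopiffalse(is(cw, "ComplexityWeights") && cw@fitted,
              "cw must be a fitted ComplexityWeights")
  C <- complexityScore(eggs[TRAIT_NAMES], cw)
  ids <- outcomes$experiment_id
  acd <- vapply(seq_along(ids), function(i) {
    rows <- eggs$experiment_id == ids[i]
    abs(C[rows & eggs$role == "experimental"][1] -
          mean(C[rows & eggs$role == "host"]))
  }, numeric(1))
  logisticFit(outcomes$outcome, data.frame(ACD = zscore(acd)))
}
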