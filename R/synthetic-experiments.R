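# Synthetic rejection experiments generated from the logistic model on the
# generalized Weber statistic |a - b| / b^k with a known true exponent, and
# a trait-level generator for weight-recovery studies.

#' Configuration of the synthetic rejection-experiment generator
#'
#' Defaults emulate the study conditions: clutches of 2--4 eggs with modal
#' size 3; a baseline rejection rate of about 0.16 (19 of 119 experiments
#' rejected, hence `beta0 = log(19/100)`); complexity on a roughly
#' 0--1000-unit scale (population mean 600, sd 200, truncated at mean/10 so
#' the clutch mean b, which appears in a denominator, stays strictly
#' positive); a within-clutch sd of 112 giving clutch repeatability (ICC)
#' near 0.76; and a rejection effect of `beta1 = 1.5` on the standardized
#' Weber statistic.
#'
#' @param nExperiments Number of experiments.
#' @param clutchSizeProbs Probabilities over clutch sizes 2, 3, 4.
#' @param trueK True Weber exponent in [-1, 2] (default 1 = Weber's law).
#' @param beta0 Log-odds intercept.
#' @param beta1 Log-odds slope on the z-scored Weber statistic.
#' @param complexityMean,complexitySD Population mean and sd of per-egg
#'   complexity.
#' @param complexityMin Lower truncation (default mean/10, must be > 0).
#' @param withinClutchSD Within-clutch complexity sd.
#' @param seed Integer seed.
#' @return A validated configuration list.
#' @export
simulationConfig <- function(nExperiments = 300,
                             clutchSizeProbs = c(0.25, 0.5, 0.25),
                             trueK = 1, beta0 = log(19 / 100), beta1 = 1.5,
                             complexityMean = 600, complexitySD = 200,
                             complexityMin = complexityMean / 10,
                             withinClutchSD = 112, seed = 1) {
  stopiffalse(nExperiments >= 1, "nExperiments must be >= 1")
  stopiffalse(length(clutchSizeProbs) == 3 && all(clutchSizeProbs >= 0) &&
                sum(clutchSizeProbs) > 0,
              "clutchSizeProbs must be 3 non-negative probabilities")
  stopiffalse(is.finite(beta1), "beta1 must be finite")
  stopiffalse(trueK >= -1 && trueK <= 2,
              "trueK must lie in the scanned range [-1, 2]")
  stopiffalse(complexityMin > 0, "complexityMin must be > 0")
  stopiffalse(withinClutchSD >= 0, "withinClutchSD must be >= 0")
  list(nExperiments = as.integer(nExperiments),
       clutchSizeProbs = clutchSizeProbs / sum(clutchSizeProbs),
       trueK = trueK, beta0 = beta0, beta1 = beta1,
       complexityMean = complexityMean, complexitySD = complexitySD,
       complexityMin = complexityMin, withinClutchSD = withinClutchSD,
       seed = as.integer(seed))
}

#' Simulate rejection experiments with a known true Weber exponent
#'
#' For each experiment a clutch-level mean complexity is drawn from a
#' truncated normal population; the retained clutch eggs scatter around it
#' with the within-clutch sd (re-drawn if below the truncation floor); the
#' experimental egg's complexity `a` is an independent draw from the same
#' population; `b` is the mean of the retained clutch eggs. Rejection is
#' Bernoulli with probability `plogis(beta0 + beta1 * z)` where `z` is the
#' across-experiment z-score of `|a - b| / b^trueK`.
#'
#' @param config Configuration from [simulationConfig()].
#' @return A long-format data.frame (one row per egg) with columns
#'   `experiment_id, clutch_id, role, egg_id, complexity, outcome, species`;
#'   collapse to one row per experiment with [experimentRecords()].
#' @export
makeExperimentSet <- function(config) {
  cfg <- config
  withSeed(cfg$seed, {
    n <- cfg$nExperiments
    sizes <- sample(2:4, n, replace = TRUE, prob = cfg$clutchSizeProbs)
    rows <- vector("list", n)
    aVals <- numeric(n); bVals <- numeric(n)
    for (i in seq_len(n)) {
      m <- rtruncnorm_low(1, cfg$complexityMean, cfg$complexitySD,
                          cfg$complexityMin)
      clutch <- m + rnorm(sizes[i], 0, cfg$withinClutchSD)
      bad <- which(clutch < cfg$complexityMin)
      guard <- 0L
      while (length(bad)) {
        clutch[bad] <- m + rnorm(length(bad), 0, cfg$withinClutchSD)
        bad <- bad[clutch[bad] < cfg$complexityMin]
        guard <- guard + 1L
        if (guard > 10000L)
          stop("internal error: clutch complexity truncation failed")
      }
      a <- rtruncnorm_low(1, cfg$complexityMean, cfg$complexitySD,
                          cfg$complexityMin)
      if (a <= 0 || any(clutch <= 0))
        stop("internal error: non-positive complexity after truncation")
      aVals[i] <- a; bVals[i] <- mean(clutch)
      eid <- sprintf("exp%03d", i)
      rows[[i]] <- data.frame(
        experiment_id = eid,
        clutch_id = sprintf("clutch%03d", i),
        role = c(rep("host", sizes[i]), "experimental"),
        egg_id = c(sprintf("%s_h%d", eid, seq_len(sizes[i])),
                   paste0(eid, "_x")),
        complexity = c(clutch, a))
    }
    w <- abs(aVals - bVals) / bVals^cfg$trueK
    z <- if (sd(w) > 0) (w - mean(w)) / sd(w) else rep(0, n)
    outcome <- rbinom(n, 1, plogis(cfg$beta0 + cfg$beta1 * z))
    out <- do.call(rbind, rows)
    out$outcome <- rep(outcome, sizes + 1L)
    out$species <- "prinia"
    rownames(out) <- NULL
    out
  })
}

#' Collapse a long egg table to one record per experiment
#'
#' @param eggs Long data.frame as produced by [makeExperimentSet()] (or
#'   [assembleExperiments()]): columns `experiment_id`, `role`,
#'   `complexity`, `outcome`.
#' @return data.frame with one row per experiment: `experiment_id`, `a`
#'   (experimental-egg complexity), `b` (mean retained clutch complexity),
#'   `clutch_size`, `outcome`.
#' @export
experimentRecords <- function(eggs) {
  need <- c("experiment_id", "role", "complexity", "outcome")
  stopiffalse(all(need %in% names(eggs)),
              paste("eggs must have columns:", paste(need, collapse = ", ")))
  ids <- unique(eggs$experiment_id)
  rec <- lapply(ids, function(id) {
    e <- eggs[eggs$experiment_id == id, ]
    host <- e$complexity[e$role == "host"]
    expc <- e$complexity[e$role == "experimental"]
    if (length(expc) != 1)
      stop("experiment ", id, " must have exactly one experimental egg")
    if (length(host) < 1)
      stop("experiment ", id, " has no retained host eggs")
    data.frame(experiment_id = id, a = expc, b = mean(host),
               clutch_size = length(host), outcome = e$outcome[1])
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Simulate experiments whose rejection depends on a single trait
#'
#' Generates per-egg six-trait tables in which only one trait carries
#' signal: clutch eggs share a clutch-level value of the informative trait
#' (plus small within-clutch scatter), the experimental egg draws its own,
#' and rejection is Bernoulli on the z-scored absolute difference in that
#' trait. All other traits are independent noise for every egg. Used to
#' check that the coefficient optimizer recovers the informative trait.
#'
#' @param nExperiments Number of experiments (default 150).
#' @param informativeTrait Index 1--6 of the signal trait.
#' @param beta0,beta1 Logistic intercept and slope on the z-scored
#'   informative-trait difference (defaults -1 and 4: a designed
#'   strong-effect recovery experiment).
#' @param clutchSize Host eggs per clutch (default 3).
#' @param seed Integer seed.
#' @return list with `eggs` (experiment_id, role, six trait columns),
#'   `outcomes` (experiment_id, outcome) and `informativeTrait`.
#' @export
makeTraitExperimentSet <- function(nExperiments = 150, informativeTrait = 1,
                                   beta0 = -1, beta1 = 4, clutchSize = 3,
                                   seed = 1) {
  stopiffalse(informativeTrait %in% 1:6, "informativeTrait must be 1..6")
  withSeed(seed, {
    n <- as.integer(nExperiments)
    nEggs <- n * (clutchSize + 1L)
    traits <- matrix(runif(nEggs * 6), nEggs, 6,
                     dimnames = list(NULL, TRAIT_NAMES))
    eid <- rep(sprintf("exp%03d", seq_len(n)), each = clutchSize + 1L)
    role <- rep(c(rep("host", clutchSize), "experimental"), n)
    clutchVal <- runif(n, 0.3, 0.7)
    expVal <- runif(n, 0.05, 0.95)
    sig <- numeric(nEggs)
    sig[role == "host"] <- rep(clutchVal, each = clutchSize) +
      rnorm(n * clutchSize, 0, 0.03)
    sig[role == "experimental"] <- expVal
    traits[, informativeTrait] <- pmin(pmax(sig, 0), 1)
    eggs <- data.frame(experiment_id = eid, role = role, traits,
                       check.names = FALSE)
    hostMean <- vapply(seq_len(n), function(i) {
      mean(traits[eid == sprintf("exp%03d", i) & role == "host",
                  informativeTrait])
    }, numeric(1))
    d <- abs(expVal - hostMean)
    z <- (d - mean(d)) / sd(d)
    outcomes <- data.frame(experiment_id = sprintf("exp%03d", seq_len(n)),
                           outcome = rbinom(n, 1, plogis(beta0 + beta1 * z)))
    list(eggs = eggs, outcomes = outcomes,
         informativeTrait = informativeTrait)
  })
}
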