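# End-to-end orchestration: YAML config, stage sequencing with per-stage
# seeds split from one master seed, CSV/JSON artefact contracts, and the
# data-assembly exclusion rules (removed eggs, duplicate females,
# clutch-size-1 experiments).

defaultRunConfig <- function() {
  list(
    stages = c("simulate", "weber"),
    out = "eggweber-run",
    seed = 1L,
    logLevel = "info",
    simulate = list(nExperiments = 300L, trueK = 1, beta0 = log(19 / 100),
                    beta1 = 1.5, clutchSizeProbs = c(0.25, 0.5, 0.25),
                    complexityMean = 600, complexitySD = 200,
                    withinClutchSD = 112, nImages = 0L),
    detector = list(contrastThreshold = 0.01, edgeRatio = 10),
    extract = list(targetPxPerMm = 29),
    traits = list(deltaMm = 1),
    optimizer = list(restarts = 50L, tol = 1e-6),
    kGrid = list(lo = -1, hi = 2, step = 0.25),
    paths = list(images = NULL, features = NULL, experiments = NULL,
                 eggs = NULL, outcomes = NULL)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline run configuration
#'
#' Reads a YAML configuration file and merges it over the package
#' defaults; every downstream default is overridable.
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @return Configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  cfg
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

logMsg <- function(level, cfg, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[cfg$logLevel %||% "info"]])
    message("[", level, "] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline stages end-to-end
#'
#' Executes the requested stages in order (`simulate`, `extract`,
#' `traits`, `optimize`, `weber`), writing per-stage artefacts (CSV
#' tables, PNG images, JSON reports) under the output directory, and a
#' single JSON run report with package version, per-stage seeds and the
#' configuration (echoed verbatim) plus its hash. All randomness flows
#' from one master seed, split deterministically per stage, so a re-run
#' with the same configuration is byte-identical.
#'
#' @param config Configuration list from [readRunConfig()], or a path to a
#'   YAML file.
#' @param seed Optional master-seed override.
#' @param out Optional output-directory override.
#' @return Invisibly, the run report list.
#' @export
runPipeline <- function(config = readRunConfig(), seed = NULL, out = NULL) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out)) cfg$out <- out
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  stageSeeds <- setNames(as.list(splitSeed(cfg$seed, 5)),
                         c("simulate", "extract", "traits", "optimize",
                           "weber"))
  # the hash covers the analysis-relevant configuration, not where the
  # artefacts happen to live
  hashCfg <- cfg[setdiff(names(cfg), c("out", "paths"))]
  report <- list(package = "eggweber",
                 version = as.character(packageVersion("eggweber")),
                 seed = cfg$seed, stageSeeds = stageSeeds,
                 config = cfg, configHash = configHash(hashCfg),
                 stages = list())
  artefacts <- list(experiments = cfg$paths$experiments,
                    eggs = cfg$paths$eggs,
                    outcomes = cfg$paths$outcomes,
                    images = cfg$paths$images,
                    features = cfg$paths$features)
  for (stage in cfg$stages) {
    res <- tryCatch(
      switch(stage,
        simulate = stageSimulate(cfg, stageSeeds$simulate, artefacts),
        extract  = stageExtract(cfg, artefacts),
        traits   = stageTraits(cfg, artefacts),
        optimize = stageOptimize(cfg, stageSeeds$optimize, artefacts),
        weber    = stageWeber(cfg, artefacts),
        stop("unknown stage: ", stage)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    artefacts <- res$artefacts
    report$stages[[stage]] <- res$report
    logMsg("info", cfg, "stage '", stage, "' complete")
  }
  jsonlite::write_json(report, file.path(cfg$out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

stageSimulate <- function(cfg, seed, artefacts) {
  s <- cfg$simulate
  sim <- simulationConfig(nExperiments = s$nExperiments, trueK = s$trueK,
                          beta0 = s$beta0, beta1 = s$beta1,
                          clutchSizeProbs = unlist(s$clutchSizeProbs),
                          complexityMean = s$complexityMean,
                          complexitySD = s$complexitySD,
                          withinClutchSD = s$withinClutchSD, seed = seed)
  eggs <- makeExperimentSet(sim)
  path <- file.path(cfg$out, "experiments.csv")
  write.csv(eggs, path, row.names = FALSE)
  nImg <- s$nImages %||% 0L
  if (nImg > 0) {
    imgDir <- file.path(cfg$out, "images")
    dir.create(imgDir, showWarnings = FALSE)
    seeds <- splitSeed(seed + 1L, nImg)
    for (i in seq_len(nImg)) {
      p <- syntheticPatternParams(seed = seeds[i])
      img <- makeEggImage(p, eggID = sprintf("sim%03d", i), side = "a")
      writeEggImage(img, file.path(imgDir, sprintf("sim%03d_a", i)))
    }
    artefacts$images <- imgDir
  }
  artefacts$experiments <- path
  list(artefacts = artefacts,
       report = list(nExperiments = s$nExperiments,
                     nRejected = sum(experimentRecords(eggs)$outcome),
                     experiments = basename(path)))
}

stageExtract <- function(cfg, artefacts) {
  stopiffalse(!is.null(artefacts$images), "extract: no image directory")
  stems <- sub("\\.json$", "",
               list.files(artefacts$images, pattern = "\\.json$",
                          full.names = TRUE))
  outDir <- file.path(cfg$out, "features")
  dir.create(outDir, showWarnings = FALSE)
  params <- siftParams(contrastThreshold = cfg$detector$contrastThreshold,
                       edgeRatio = cfg$detector$edgeRatio)
  counts <- integer(length(stems))
  target <- cfg$extract$targetPxPerMm %||% 29
  for (i in seq_along(stems)) {
    img <- readEggImage(stems[i])
    img <- rescaleToCanonical(img, target)
    fs <- detectFeatures(img, params)
    counts[i] <- featureCount(fs)
    writeFeatures(fs, file.path(outDir, paste0(basename(stems[i]),
                                               "_features.csv")))
  }
  artefacts$features <- outDir
  list(artefacts = artefacts,
       report = list(nImages = length(stems), detector = params,
                     featureCounts = counts))
}

stageTraits <- function(cfg, artefacts) {
  stopiffalse(!is.null(artefacts$images) && !is.null(artefacts$features),
              "traits: need images and features")
  stems <- sub("\\.json$", "",
               list.files(artefacts$images, pattern = "\\.json$",
                          full.names = TRUE))
  rows <- lapply(stems, function(st) {
    img <- rescaleToCanonical(readEggImage(st),
                              cfg$extract$targetPxPerMm %||% 29)
    fs <- readFeatures(file.path(artefacts$features,
                                 paste0(basename(st), "_features.csv")),
                       eggID = img@eggID, side = img@side,
                       pxPerMm = img@pxPerMm)
    tv <- computeTraits(img, fs, delta = cfg$traits$deltaMm * img@pxPerMm)
    data.frame(egg_id = img@eggID, side = img@side, t(tv))
  })
  tab <- do.call(rbind, rows)
  path <- file.path(cfg$out, "traits.csv")
  write.csv(tab, path, row.names = FALSE)
  artefacts$traits <- path
  list(artefacts = artefacts, report = list(nSides = nrow(tab),
                                            traits = basename(path)))
}

stageOptimize <- function(cfg, seed, artefacts) {
  stopiffalse(!is.null(artefacts$eggs) && !is.null(artefacts$outcomes),
              "optimize: need per-egg trait table and outcomes")
  eggs <- read.csv(artefacts$eggs)
  outcomes <- read.csv(artefacts$outcomes)
  cw <- optimizeWeights(eggs, outcomes,
                        restarts = cfg$optimizer$restarts,
                        tol = cfg$optimizer$tol, seed = seed)
  path <- file.path(cfg$out, "weights.json")
  jsonlite::write_json(
    list(weights = as.list(cw@weights),
         standardization = list(min = as.list(cw@standardization@traitMin),
                                max = as.list(cw@standardization@traitMax),
                                dropped = as.list(cw@standardization@dropped)),
         epsilon = cw@epsilon, scaleUnits = cw@scaleUnits,
         optim = cw@optimInfo),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artefacts$weights <- path
  list(artefacts = artefacts,
       report = list(weights = as.list(cw@weights),
                     objective = cw@optimInfo$objective,
                     weightsFile = basename(path)))
}

stageWeber <- function(cfg, artefacts) {
  stopiffalse(!is.null(artefacts$experiments), "weber: no experiments CSV")
  eggs <- read.csv(artefacts$experiments)
  rec <- computePredictors(experimentRecords(eggs))
  y <- rec$outcome
  sel <- allSubsetsSelection(y, rec[c("zACD", "zRCD", "zHC")])
  fitACD <- logisticFit(y, rec["zACD"])
  fitRCD <- logisticFit(y, rec["zRCD"])
  fitBoth <- logisticFit(y, rec[c("zACD", "zRCD")])
  kGrid <- seq(cfg$kGrid$lo, cfg$kGrid$hi, by = cfg$kGrid$step)
  scan <- kScan(y, rec$a, rec$b, kGrid)
  # the polynomial minimum needs >= 7 grid points; short diagnostic grids
  # keep the raw scan only
  if (sum(scan@valid) >= 7) scan <- kMinimum(scan)
  scanCSV <- file.path(cfg$out, "kscan.csv")
  write.csv(data.frame(k = scan@k, aic = scan@aic, valid = scan@valid),
            scanCSV, row.names = FALSE)
  hp <- hierarchicalPartitioning(y, rec[c("zACD", "zRCD")])
  rep <- list(
    n = nrow(rec),
    nRejected = sum(y),
    selection = sel,
    lrtAddRCD = lrt(fitACD, fitBoth),
    lrtAddACD = lrt(fitRCD, fitBoth),
    vifACDRCD = as.list(vif(fitBoth)),
    pearsonACDRCD = pearsonCI(rec$ACD, rec$RCD),
    hierarchicalPartitioning = list(percent = as.list(hp$percent),
                                    fullR2 = hp$fullR2),
    kMin = scan@kMin, aicMin = scan@aicMin,
    ciLow = scan@ciLow, ciHigh = scan@ciHigh,
    ciOpenLow = scan@ciOpenLow, ciOpenHigh = scan@ciOpenHigh,
    kscanFile = basename(scanCSV))
  path <- file.path(cfg$out, "weber_report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  artefacts$weberReport <- path
  list(artefacts = artefacts, report = rep)
}

#' Assemble analysis-ready experiments from raw tables
#'
#' Applies the data-assembly rules: eggs flagged as removed (replaced by
#' the experimental egg) are excluded from the clutch means; when the same
#' female appears in more than one experiment, one experiment per female is
#' retained (seeded random choice); and experiments whose host clutch had
#' only one egg are excluded, because a clutch of one has no egg left once
#' the replaced egg is excluded from the mean. Every exclusion is logged in
#' the returned `excluded` table.
#'
#' @param eggs Long data.frame: `experiment_id`, `role`, `egg_id`,
#'   `complexity`, `outcome`, optional `female_id` and logical `removed`.
#' @param seed Seed for the duplicate-female choice.
#' @return list with `eggs` (retained rows), `records` (per-experiment
#'   table from [experimentRecords()]) and `excluded`
#'   (experiment_id/egg_id, reason).
#' @export
assembleExperiments <- function(eggs, seed = 1) {
  excluded <- data.frame(id = character(), reason = character())
  origSizes <- tapply(eggs$role == "host", eggs$experiment_id, sum)
  if (!is.null(eggs$removed)) {
    drop <- which(eggs$removed & eggs$role == "host")
    if (length(drop)) {
      excluded <- rbind(excluded,
                        data.frame(id = eggs$egg_id[drop],
                                   reason = "removed egg"))
      eggs <- eggs[-drop, ]
    }
  }
  if (!is.null(eggs$female_id)) {
    perExp <- unique(eggs[c("experiment_id", "female_id")])
    dup <- split(perExp$experiment_id, perExp$female_id)
    dup <- dup[vapply(dup, length, integer(1)) > 1]
    dropIDs <- withSeed(seed, unlist(lapply(dup, function(ids)
      sample(ids, length(ids) - 1))))
    if (length(dropIDs)) {
      excluded <- rbind(excluded,
                        data.frame(id = dropIDs,
                                   reason = "duplicate female"))
      eggs <- eggs[!eggs$experiment_id %in% dropIDs, ]
    }
  }
  retained <- tapply(eggs$role == "host", eggs$experiment_id, sum)
  small <- names(retained)[retained < 1 |
                             origSizes[names(retained)] <= 1]
  if (length(small)) {
    excluded <- rbind(excluded,
                      data.frame(id = small, reason = "host clutch size 1"))
    eggs <- eggs[!eggs$experiment_id %in% small, ]
  }
  list(eggs = eggs, records = experimentRecords(eggs), excluded = excluded)
}
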