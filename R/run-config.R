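# Run-level configuration, seeding and replicate orchestration. Configs
# round-trip through YAML; omitted keys fall back to the full-program
# defaults (7 chromosomes, 1000 SNPs + 100 QTL per chromosome, 20 varieties
# of 200, plot heritabilities 0.3/0.6/0.4/0.2, 50 replicates).

runConfigDefaults <- function() {
  list(
    scenarios = "Phen-Y12",
    replicates = 50L,
    seed = 1L,
    profile = "fast",
    outDir = "ryegrassGS-results",
    overwrite = FALSE,
    genome = list(
      nChromosomes = 7L, chromLengthCM = 100, nSnpPerChrom = 1000L,
      nQtlPerChrom = 100L, nLociPerChrom = 2500L, mutationRate = 2.5e-5,
      mafMin = 0.05
    ),
    history = list(nGenerations = 2000L, sizeFrom = 2000L, sizeTo = 1000L,
                   constantFor = 1000L),
    varieties = list(count = 20L, size = 200L),
    traits = list(targetPlotH2 = c(0.3, 0.6, 0.4, 0.2), rho34 = 0.7),
    calibrationPlots = 250L,
    program = list(
      years = 36L, nCycles = 25L, nF1Families = 250L, familySize = 40L,
      nSelF2 = 50L, spFamilySize = 40L, nSPSelected = 400L, groupSize = 8L,
      synSize = 40L, nSynSelected = 20L, plotSampleSize = 20L
    )
  )
}

mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be a mapping")
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validateRunConfig <- function(cfg) {
  bad <- setdiff(cfg$scenarios, scenarioNames)
  if (length(bad) > 0)
    stop("invalid scenario name(s): ", paste(bad, collapse = ", "))
  if (cfg$replicates < 1L) stop("replicates must be positive")
  if (!cfg$profile %in% c("fast", "full"))
    stop("profile must be 'fast' or 'full'")
  if (cfg$varieties$count < 2L) stop("at least 2 initial varieties required")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration and fills omitted keys with the full-program
#' defaults. Unknown keys and invalid scenario names raise named errors.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `RunConfig` list.
#' @seealso [saveRunConfig()], [runReplicates()]
#' @export
loadRunConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- mergeConfig(runConfigDefaults(), user)
  cfg$replicates <- as.integer(cfg$replicates)
  cfg$seed <- as.integer(cfg$seed)
  validateRunConfig(cfg)
  structure(cfg, class = "RunConfig")
}

#' Save a run configuration
#'
#' @param cfg a `RunConfig`.
#' @param path output YAML path.
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Deterministic per-replicate seeds below 2^31.
replicateSeeds <- function(baseSeed, n) {
  (as.integer(baseSeed) + 1000L * seq_len(n)) %% .Machine$integer.max
}

#' Run replicated scenario simulations
#'
#' Simulates the historical population once (it is shared by every
#' replicate and scenario), then runs each requested scenario for the
#' requested number of independent replicates; each replicate re-draws the
#' varieties, trait architecture and breeding program under its own
#' deterministic seed. Per-replicate metric tables and across-replicate
#' aggregates (mean and SD) are written as CSV under `cfg$outDir`.
#'
#' @param cfg a `RunConfig` from [loadRunConfig()].
#' @param verbose print progress.
#' @return The output directory, invisibly.
#' @export
runReplicates <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (dir.exists(cfg$outDir) && !isTRUE(cfg$overwrite) &&
      length(list.files(cfg$outDir)) > 0)
    stop("output directory '", cfg$outDir,
         "' exists and is not empty; set overwrite: true")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  spec <- do.call(genomeSpec, cfg$genome)
  set.seed(cfg$seed)
  hist <- simulateHistoricalPopulation(
    spec, cfg$history$nGenerations,
    do.call(defaultSizeSchedule, cfg$history)
  )
  panel <- buildLocusPanel(hist, spec)
  founders <- subsetLoci(hist, panel)
  rm(hist)

  seeds <- replicateSeeds(cfg$seed, cfg$replicates)
  for (scen in cfg$scenarios) {
    scenDir <- file.path(cfg$outDir, scen)
    dir.create(scenDir, showWarnings = FALSE)
    gainAll <- varAll <- accAll <- list()
    for (r in seq_len(cfg$replicates)) {
      if (verbose) message(scen, " replicate ", r, "/", cfg$replicates)
      set.seed(seeds[r])
      varieties <- createInitialVarieties(founders, cfg$varieties$count,
                                          cfg$varieties$size)
      arch <- sampleQtlEffects(panel,
                               defaultEffectCorr(cfg$traits$rho34),
                               cfg$traits$targetPlotH2)
      arch <- calibrateArchitecture(varieties, arch,
                                    nPlots = cfg$calibrationPlots,
                                    familySize = cfg$program$familySize)
      sc <- do.call(scenarioConfig, c(list(name = scen,
                                           chain = chainProfile(cfg$profile)),
                                      cfg$program))
      res <- runScenario(sc, panel, varieties, arch)

      repDir <- file.path(scenDir, sprintf("rep%03d", r))
      dir.create(repDir, showWarnings = FALSE)
      write.csv(res$gain, file.path(repDir, "gain.csv"), row.names = FALSE)
      write.csv(res$additiveVariance, file.path(repDir, "variance.csv"),
                row.names = FALSE)
      write.csv(res$accuracy, file.path(repDir, "accuracy.csv"),
                row.names = FALSE)
      if (nrow(res$referenceSize) > 0)
        write.csv(res$referenceSize,
                  file.path(repDir, "reference_size.csv"),
                  row.names = FALSE)
      gainAll[[r]] <- transform(res$gain, replicate = r)
      varAll[[r]] <- transform(res$additiveVariance, replicate = r)
      accAll[[r]] <- if (nrow(res$accuracy) > 0)
        transform(res$accuracy, replicate = r) else NULL
    }
    writeAggregate(do.call(rbind, gainAll), c("cycle", "trait"), "deltaG",
                   file.path(scenDir, "gain_summary.csv"))
    writeAggregate(do.call(rbind, varAll), c("cycle", "trait"),
                   "standardized", file.path(scenDir, "variance_summary.csv"))
    acc <- do.call(rbind, accAll)
    if (!is.null(acc) && nrow(acc) > 0)
      writeAggregate(acc, c("cycle", "stage", "trait"), "r",
                     file.path(scenDir, "accuracy_summary.csv"))
  }
  invisible(cfg$outDir)
}

# Mean and SD of `value` over replicates within the grouping keys.
writeAggregate <- function(df, keys, value, path) {
  agg <- aggregate(df[[value]], df[keys],
                   function(v) c(mean = mean(v), sd = sd(v)))
  out <- cbind(agg[keys], mean = agg$x[, "mean"], sd = agg$x[, "sd"])
  write.csv(out[do.call(order, out[keys]), ], path, row.names = FALSE)
  invisible(path)
}

#' Calibrate a trait architecture on simulated F2 plots
#'
#' Generates a calibration set of F2-style plots from the initial
#' varieties (pair-cross two random plants from two random varieties,
#' intermate the F1 family, average member TBVs) and calibrates the
#' residual variances to the target plot heritabilities with
#' [calibrateToPlotH2()].
#'
#' @param varieties list of initial-variety [Cohort-class] objects.
#' @param arch an uncalibrated [TraitArchitecture-class].
#' @param nPlots calibration plots (default 250).
#' @param familySize plants per F1 family and per plot.
#' @return The calibrated architecture.
#' @export
calibrateArchitecture <- function(varieties, arch, nPlots = 250L,
                                  familySize = 40L) {
  ptbv <- simulateF2PlotTbvs(varieties, arch, nPlots, familySize)
  calibrateToPlotH2(ptbv, arch)
}

# F2 plot mean TBVs under the cycle-1 crossing design.
simulateF2PlotTbvs <- function(varieties, arch, nPlots, familySize) {
  f1 <- makeF1Families(varieties, nPlots, familySize, cycle = 0L)
  f2 <- intermateBlocks(f1, nPlots, familySize, familySize, "F2",
                        unique(f1@lineage$family), 0L)
  tbv <- computeTbv(f2, arch)
  rowsum(tbv, rep(seq_len(nPlots), each = familySize)) / familySize
}
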