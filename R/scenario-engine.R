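# The overlapping-cycle breeding program: one 12-year cycle is launched per
# year; five scenarios differ in how new-cycle parents are recruited and in
# whether selection uses plot phenotypes or GEBVs.

scenarioNames <- c("Phen-Y12", "Phen", "GS-Y12", "GS", "GS-SP")

#' Scenario configuration
#'
#' Assembles and validates the knobs of a breeding-program scenario.
#' Defaults reproduce the full program: 36 years, 25 overlapping cycles,
#' 250 F1 families of 40, 50 selected F2 families, 400 polycross parents in
#' 50 groups of 8, 20 selected SYN2 groups, plots genotyped as mean dosage
#' of 20 sampled plants. `independentCycles` (cycles whose parents come
#' from the initial varieties) is 11 for the Y12 scenarios and 5 otherwise.
#'
#' Scenario semantics: `Phen-Y12`/`Phen` select on plot phenotypes and
#' recruit later-cycle parents from SYN2 groups only (`Phen-Y12`) or from
#' F2 single plants plus SYN2 groups (`Phen`); `GS-Y12`/`GS` are their
#' genomic counterparts selecting on GEBVs; `GS-SP` replaces SYN2 groups
#' with individually genotyped SYN2 single plants in the parent pool.
#'
#' @param name one of `"Phen-Y12"`, `"Phen"`, `"GS-Y12"`, `"GS"`,
#'   `"GS-SP"`.
#' @param years program length in years.
#' @param nCycles number of cycles launched (one per year).
#' @param nF1Families,familySize F1 families per cycle and plants per
#'   family (also the F2 plot size).
#' @param nSelF2 F2 families kept at the first selection.
#' @param spFamilySize greenhouse single plants grown per selected family.
#' @param nSPSelected single plants kept as polycross parents (must be a
#'   multiple of `groupSize`).
#' @param groupSize parents per synthetic group.
#' @param synSize plants per SYN1/SYN2 group.
#' @param nSynSelected SYN2 groups kept at the second selection.
#' @param plotSampleSize plants sampled per plot for dosage genotyping.
#' @param indexTraits,indexWeights traits and weights of the selection
#'   index.
#' @param chain Gibbs [chainProfile()] for the GS scenarios.
#' @param independentCycles override for the number of cycles started from
#'   the initial varieties (defaults by scenario name).
#' @param doSyn3 produce the terminal SYN3 generation (it feeds nothing).
#' @return A validated `ScenarioConfig` list.
#' @export
scenarioConfig <- function(name = "Phen-Y12", years = 36L, nCycles = 25L,
                           nF1Families = 250L, familySize = 40L,
                           nSelF2 = 50L, spFamilySize = 40L,
                           nSPSelected = 400L, groupSize = 8L,
                           synSize = 40L, nSynSelected = 20L,
                           plotSampleSize = 20L,
                           indexTraits = c(1L, 3L, 4L),
                           indexWeights = NULL,
                           chain = chainProfile("fast"),
                           independentCycles = NULL,
                           doSyn3 = TRUE) {
  if (!name %in% scenarioNames)
    stop("unknown scenario '", name, "'; must be one of: ",
         paste(scenarioNames, collapse = ", "))
  if (is.null(independentCycles))
    independentCycles <- if (grepl("Y12$", name)) 11L else 5L
  if (is.null(indexWeights))
    indexWeights <- rep(1 / length(indexTraits), length(indexTraits))

  cfg <- list(
    name = name,
    genomic = grepl("^GS", name),
    parentSources = switch(name,
      "Phen-Y12" = "syn2plants",
      "GS-Y12" = "syn2plants",
      "Phen" = c("f2sp", "syn2plants"),
      "GS" = c("f2sp", "syn2plants"),
      "GS-SP" = c("f2sp", "syn2sp")
    ),
    years = as.integer(years),
    nCycles = as.integer(nCycles),
    independentCycles = as.integer(independentCycles),
    nF1Families = as.integer(nF1Families),
    familySize = as.integer(familySize),
    nSelF2 = as.integer(nSelF2),
    spFamilySize = as.integer(spFamilySize),
    nSPSelected = as.integer(nSPSelected),
    groupSize = as.integer(groupSize),
    nSyn = as.integer(nSPSelected) %/% as.integer(groupSize),
    synSize = as.integer(synSize),
    nSynSelected = as.integer(nSynSelected),
    plotSampleSize = as.integer(plotSampleSize),
    nParents = 2L * as.integer(nF1Families),
    indexTraits = as.integer(indexTraits),
    indexWeights = indexWeights,
    chain = chainProfile(chain),
    doSyn3 = isTRUE(doSyn3)
  )
  with(cfg, {
    if (nSPSelected %% groupSize != 0L)
      stop("nSPSelected must be a multiple of groupSize")
    if (nSelF2 > nF1Families) stop("nSelF2 exceeds nF1Families")
    if (nSPSelected > nSelF2 * spFamilySize)
      stop("nSPSelected exceeds the available single plants")
    if (nSynSelected > nSyn) stop("nSynSelected exceeds the SYN groups")
    if (plotSampleSize > familySize || plotSampleSize > synSize)
      stop("plotSampleSize exceeds the plot size")
    if (nCycles > years) stop("nCycles cannot exceed years")
  })
  structure(cfg, class = "ScenarioConfig")
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat("ScenarioConfig '", x$name, "': ", x$years, " years, ", x$nCycles,
      " cycles (", x$independentCycles, " independent)\n", sep = "")
  cat("  ", x$nF1Families, "F1 families x", x$familySize, "->",
      x$nSelF2, "selected;", x$nSPSelected, "SPs in", x$nSyn,
      "groups of", x$groupSize, "->", x$nSynSelected, "SYN2\n")
  invisible(x)
}

#' Within-cycle event calendar
#'
#' Year offsets of the events of one 12-year breeding cycle starting in
#' year `cycleStartYear`: F1 crossing in the start year, F2 plot phenotypes
#' complete after 3 years, F2 family and single-plant selection the year
#' after, single plants available as parents one further year on, SYN2
#' phenotyping/genotyping 9 years in, SYN2 selection after 10, and SYN2
#' material (with the terminal SYN3) available after 11.
#'
#' @param cycleStartYear the cycle's start year (= its cycle index when one
#'   cycle starts per year).
#' @return Named integer vector of absolute event years.
#' @export
eventCalendar <- function(cycleStartYear) {
  cycleStartYear <- as.integer(cycleStartYear)
  if (cycleStartYear < 1L) stop("cycle start year must be >= 1")
  c(
    f1Cross = cycleStartYear,
    f2Phenotype = cycleStartYear + 3L,
    f2Selection = cycleStartYear + 4L,
    f2SpAvailable = cycleStartYear + 5L,
    syn2Phenotype = cycleStartYear + 9L,
    syn2Selection = cycleStartYear + 10L,
    syn2Available = cycleStartYear + 11L,
    syn3 = cycleStartYear + 11L
  )
}

# ---- internal engine helpers -----------------------------------------

# Distinct within-block parent pairs for contiguous equally sized blocks.
blockPairs <- function(nBlocks, blockSize, nOff) {
  total <- nBlocks * nOff
  mo <- sample.int(blockSize, total, replace = TRUE)
  fa <- sample.int(blockSize, total, replace = TRUE)
  bad <- which(fa == mo)
  while (length(bad) > 0) {
    fa[bad] <- sample.int(blockSize, length(bad), replace = TRUE)
    bad <- bad[fa[bad] == mo[bad]]
  }
  base <- rep((seq_len(nBlocks) - 1L) * blockSize, each = nOff)
  list(mo = base + mo, fa = base + fa)
}

# Intermate contiguous blocks of a cohort in one mating call.
intermateBlocks <- function(cohort, nBlocks, blockSize, nOff, stage,
                            famLabels, cycle) {
  pr <- blockPairs(nBlocks, blockSize, nOff)
  mateCohort(cohort, pr$mo, pr$fa,
             ids = sprintf("%s_%s%d", rep(famLabels, each = nOff), stage,
                           rep(seq_len(nOff), nBlocks)),
             family = rep(famLabels, each = nOff),
             cycle = cycle, stage = stage)
}

# Polycross arbitrary index groups of a parent cohort in one mating call.
polycrossGroups <- function(parents, groups, nOff, groupLabels, cycle) {
  gmat <- matrix(unlist(groups), nrow = length(groups[[1]]))
  nG <- length(groups)
  gi <- rep(seq_len(nG), each = nOff)
  total <- nG * nOff
  mo <- sample.int(nrow(gmat), total, replace = TRUE)
  fa <- sample.int(nrow(gmat), total, replace = TRUE)
  bad <- which(fa == mo)
  while (length(bad) > 0) {
    fa[bad] <- sample.int(nrow(gmat), length(bad), replace = TRUE)
    bad <- bad[fa[bad] == mo[bad]]
  }
  mateCohort(parents, gmat[cbind(mo, gi)], gmat[cbind(fa, gi)],
             ids = sprintf("%s_SYN1_%d", rep(groupLabels, each = nOff),
                           rep(seq_len(nOff), nG)),
             family = rep(groupLabels, each = nOff),
             cycle = cycle, stage = "SYN1")
}

# Plot summaries of contiguous equally sized family blocks: mean TBV,
# phenotype, and (genomic only) sampled mean allele dosage.
summarizePlots <- function(cohort, nBlocks, blockSize, arch, panel,
                           genomic, plotSampleSize) {
  tbv <- computeTbv(cohort, arch)
  grp <- rep(seq_len(nBlocks), each = blockSize)
  ptbv <- rowsum(tbv, grp) / blockSize
  ppheno <- plotPhenotype(ptbv, arch)
  pdos <- NULL
  if (genomic) {
    snps <- snpIndices(panel)
    pdos <- matrix(0, nBlocks, length(snps))
    for (b in seq_len(nBlocks)) {
      cols <- (b - 1L) * blockSize + seq_len(blockSize)
      keep <- sort(sample(cols, plotSampleSize))
      hcols <- as.vector(rbind(2L * keep - 1L, 2L * keep))
      pdos[b, ] <- 2 * cpp_allele_freq(
        cohort@haplo[snps, hcols, drop = FALSE])
    }
  }
  list(tbv = tbv, plotTbv = ptbv, plotPheno = ppheno, plotDosage = pdos)
}

# Pair up parent slots (indices into a pool, possibly repeated when the
# pool is smaller than the demand). Two distinct plants per pair is a hard
# constraint (self-incompatibility); different families is preferred.
pairParents <- function(slots, fams) {
  slots <- slots[sample.int(length(slots))]
  half <- length(slots) %/% 2L
  mo <- slots[seq_len(half)]
  fa <- slots[half + seq_len(half)]
  for (i in seq_len(half)) {
    if (mo[i] != fa[i] && fams[mo[i]] != fams[fa[i]]) next
    cand <- which(seq_len(half) > i & fa != mo[i])
    if (length(cand) > 0) {
      pref <- cand[fams[fa[cand]] != fams[mo[i]]]
      j <- if (length(pref) > 0) pref[1] else cand[1]
      tmp <- fa[i]; fa[i] <- fa[j]; fa[j] <- tmp
    }
  }
  bad <- which(mo == fa)
  for (i in bad) {
    alt <- which(slots != mo[i])
    if (length(alt) > 0) fa[i] <- slots[alt[1]]
  }
  list(mo = mo, fa = fa)
}

# ---- the engine -------------------------------------------------------

#' Run one breeding-program scenario
#'
#' Simulates `cfg$years` years of an overlapping breeding program: a new
#' 12-year cycle starts every year (up to `cfg$nCycles`), early cycles
#' recruit parents from the initial varieties, later cycles from the
#' archives named by the scenario, and genomic scenarios train Bayesian
#' ridge regression on the growing plot reference population at each
#' selection event. True breeding values are used only for metrics;
#' phenotypic scenarios never see genotypes and genomic scenarios never
#' select on TBVs.
#'
#' @param cfg a [scenarioConfig()].
#' @param panel the founder [LocusPanel-class].
#' @param varieties list of initial-variety [Cohort-class] objects.
#' @param arch a calibrated [TraitArchitecture-class].
#' @param verbose print a line per year.
#' @return A `ScenarioResult` list: `gain` (per cycle and trait, mean F1
#'   TBV and cumulative gain in cycle-1 genetic SDs), `additiveVariance`
#'   (per cycle and trait, variance of F1 family mean TBVs, raw and
#'   standardized to cycle 1), `accuracy` (per cycle, stage and trait),
#'   `referenceSize` (per year, genomic scenarios), and the config.
#' @export
runScenario <- function(cfg, panel, varieties, arch, verbose = FALSE) {
  stopifnot(inherits(cfg, "ScenarioConfig"), is(panel, "LocusPanel"),
            is(arch, "TraitArchitecture"))
  if (any(is.na(arch@sigmaE2)))
    stop("trait architecture must be calibrated before running a scenario")
  nTraits <- ncol(arch@alpha)
  traitNames <- colnames(arch@alpha)
  if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(nTraits))

  cycles <- vector("list", cfg$nCycles)
  archive <- list(f2sp = list(), syn2plants = list(), syn2sp = list())
  availYear <- list(f2sp = integer(0), syn2plants = integer(0),
                    syn2sp = integer(0))
  ref <- if (cfg$genomic)
    newReferencePopulation(length(snpIndices(panel)), nTraits) else NULL
  fitCache <- new.env(parent = emptyenv())

  f1Mean <- matrix(NA_real_, cfg$nCycles, nTraits,
                   dimnames = list(NULL, traitNames))
  famVar <- matrix(NA_real_, cfg$nCycles, nTraits,
                   dimnames = list(NULL, traitNames))
  f1Cycle1Sd <- rep(NA_real_, nTraits)
  accRows <- list()
  refRows <- list()

  getFit <- function(cutoffYear) {
    key <- as.character(cutoffYear)
    if (!is.null(fitCache[[key]])) return(fitCache[[key]])
    sub <- referenceAsOf(ref, cutoffYear)
    if (nrow(sub@X) < 2L) return(NULL)
    est <- fitBrr(sub, traits = cfg$indexTraits, chain = cfg$chain)
    fitCache[[key]] <- est
    est
  }

  recordAcc <- function(cycle, year, stage, est, tbv) {
    r <- selectionAccuracy(est, tbv)
    accRows[[length(accRows) + 1L]] <<- data.frame(
      cycle = cycle, year = year, stage = stage,
      trait = traitNames[cfg$indexTraits], r = r,
      stringsAsFactors = FALSE
    )
  }

  idxScore <- function(values) {
    selectionIndex(values, traits = seq_along(cfg$indexTraits),
                   weights = cfg$indexWeights)
  }

  for (year in seq_len(cfg$years)) {
    if (verbose) message("year ", year)

    ## -- phenotype-completion events (reference additions first) ------

    cF2 <- year - 3L
    if (cF2 >= 1L && cF2 <= cfg$nCycles && !is.null(cycles[[cF2]]$f1)) {
      cyc <- cycles[[cF2]]
      f2 <- intermateBlocks(cyc$f1, cfg$nF1Families, cfg$familySize,
                            cfg$familySize, "F2",
                            unique(cyc$f1@lineage$family), cF2)
      s <- summarizePlots(f2, cfg$nF1Families, cfg$familySize, arch, panel,
                          cfg$genomic, cfg$plotSampleSize)
      cyc$f2PlotTbv <- s$plotTbv
      cyc$f2PlotPheno <- s$plotPheno
      cyc$f2PlotDosage <- s$plotDosage
      if (cfg$genomic) {
        ref <- updateReference(ref, s$plotDosage,
                               s$plotPheno,
                               id = sprintf("C%dF2_%d", cF2,
                                            seq_len(cfg$nF1Families)),
                               stage = "F2", cycle = cF2, year = year)
      }
      cycles[[cF2]] <- cyc
      rm(f2, s)
    }

    cS2 <- year - 9L
    if (cS2 >= 1L && cS2 <= cfg$nCycles && !is.null(cycles[[cS2]]$syn1)) {
      cyc <- cycles[[cS2]]
      syn2 <- intermateBlocks(cyc$syn1, cfg$nSyn, cfg$synSize, cfg$synSize,
                              "SYN2", unique(cyc$syn1@lineage$family), cS2)
      s <- summarizePlots(syn2, cfg$nSyn, cfg$synSize, arch, panel,
                          cfg$genomic, cfg$plotSampleSize)
      cyc$syn2 <- syn2
      cyc$syn2Tbv <- s$tbv
      cyc$syn2PlotTbv <- s$plotTbv
      cyc$syn2PlotPheno <- s$plotPheno
      cyc$syn2PlotDosage <- s$plotDosage
      cyc$syn1 <- NULL
      if (cfg$genomic) {
        ref <- updateReference(ref, s$plotDosage, s$plotPheno,
                               id = sprintf("C%dSYN2_%d", cS2,
                                            seq_len(cfg$nSyn)),
                               stage = "SYN2", cycle = cS2, year = year)
      }
      cycles[[cS2]] <- cyc
      rm(syn2, s)
    }

    if (cfg$genomic)
      refRows[[length(refRows) + 1L]] <-
        data.frame(year = year, nRecords = nrow(ref@X))

    ## -- F2 family + single-plant selection (cycle year - 4) ----------

    cSel <- year - 4L
    if (cSel >= 1L && cSel <= cfg$nCycles &&
        !is.null(cycles[[cSel]]$f2PlotTbv)) {
      cyc <- cycles[[cSel]]
      if (cfg$genomic) {
        est <- getFit(year - 1L)  # marker effects trained over the winter
        plotGebv <- computeGebv(cyc$f2PlotDosage, est)
        recordAcc(cSel, year, "F2_plot", plotGebv,
                  cyc$f2PlotTbv[, cfg$indexTraits])
        selFam <- selectTop(idxScore(plotGebv), cfg$nSelF2)
      } else {
        recordAcc(cSel, year, "F2_plot",
                  cyc$f2PlotPheno[, cfg$indexTraits],
                  cyc$f2PlotTbv[, cfg$indexTraits])
        selFam <- selectTop(idxScore(cyc$f2PlotPheno[, cfg$indexTraits]),
                            cfg$nSelF2)
      }
      selFam <- sort(selFam)

      # greenhouse single plants for the selected families
      famLabs <- unique(cyc$f1@lineage$family)[selFam]
      keepIdx <- as.vector(vapply(selFam, function(f)
        (f - 1L) * cfg$familySize + seq_len(cfg$familySize),
        integer(cfg$familySize)))
      f1Sel <- cyc$f1[keepIdx]
      sp <- intermateBlocks(f1Sel, cfg$nSelF2, cfg$familySize,
                            cfg$spFamilySize, "SP", famLabs, cSel)
      spTbv <- computeTbv(sp, arch)

      if (cfg$genomic) {
        spGebv <- computeGebv(snpGenotypes(sp, panel), est)
        recordAcc(cSel, year, "F2_SP", spGebv, spTbv[, cfg$indexTraits])
        selSp <- selectTop(idxScore(spGebv), cfg$nSPSelected, ids = sp@id)
      } else {
        # random choice of 8 single plants per selected family
        selSp <- as.vector(vapply(seq_len(cfg$nSelF2), function(b)
          (b - 1L) * cfg$spFamilySize +
            sample.int(cfg$spFamilySize, cfg$groupSize),
          integer(cfg$groupSize)))
      }
      spSel <- sp[selSp]
      spSelTbv <- spTbv[selSp, , drop = FALSE]

      # heading-date grouping (trait 2) and polycross into SYN1
      hd <- singlePlantPhenotype(spSelTbv, arch, trait = 2L)
      grouping <- groupByHeading(hd, cfg$groupSize, ids = spSel@id)
      groupLabs <- sprintf("C%dG%d", cSel, seq_len(cfg$nSyn))
      cyc$syn1 <- polycrossGroups(spSel, grouping$groups, cfg$synSize,
                                  groupLabs, cSel)

      # archive the polycross parents as next-cycle material
      archive$f2sp[[as.character(cSel)]] <- spSel
      availYear$f2sp[as.character(cSel)] <- year + 1L

      cyc$f1 <- NULL
      cyc$f2PlotDosage <- NULL
      cycles[[cSel]] <- cyc
      rm(sp, spTbv, f1Sel)
    }

    ## -- SYN2 selection (cycle year - 10) ------------------------------

    cS2s <- year - 10L
    if (cS2s >= 1L && cS2s <= cfg$nCycles &&
        !is.null(cycles[[cS2s]]$syn2PlotTbv)) {
      cyc <- cycles[[cS2s]]
      if (cfg$genomic) {
        est <- getFit(year)
        plotGebv <- computeGebv(cyc$syn2PlotDosage, est)
        recordAcc(cS2s, year, "SYN2_plot", plotGebv,
                  cyc$syn2PlotTbv[, cfg$indexTraits])
        selSyn <- selectTop(idxScore(plotGebv), cfg$nSynSelected)
      } else {
        recordAcc(cS2s, year, "SYN2_plot",
                  cyc$syn2PlotPheno[, cfg$indexTraits],
                  cyc$syn2PlotTbv[, cfg$indexTraits])
        # plant-level pairing: every SYN2 plant's TBV against its plot's
        # phenotype; within-group Mendelian variance dilutes this towards
        # the low, cycle-constant accuracy typical of phenotypic schemes
        recordAcc(cS2s, year, "SYN2_plant",
                  cyc$syn2PlotPheno[rep(seq_len(cfg$nSyn),
                                        each = cfg$synSize),
                                    cfg$indexTraits],
                  cyc$syn2Tbv[, cfg$indexTraits])
        selSyn <- selectTop(idxScore(cyc$syn2PlotPheno[, cfg$indexTraits]),
                            cfg$nSynSelected)
      }
      selSyn <- sort(selSyn)
      keepIdx <- as.vector(vapply(selSyn, function(g)
        (g - 1L) * cfg$synSize + seq_len(cfg$synSize),
        integer(cfg$synSize)))
      syn2Sel <- cyc$syn2[keepIdx]

      archive$syn2plants[[as.character(cS2s)]] <- syn2Sel
      availYear$syn2plants[as.character(cS2s)] <- year + 1L

      if (cfg$name == "GS-SP") {
        # greenhouse SYN2 single plants of the selected groups
        syn2sp <- intermateBlocks(syn2Sel, cfg$nSynSelected, cfg$synSize,
                                  cfg$spFamilySize, "S2SP",
                                  unique(syn2Sel@lineage$family), cS2s)
        sTbv <- computeTbv(syn2sp, arch)
        sGebv <- computeGebv(snpGenotypes(syn2sp, panel), est)
        recordAcc(cS2s, year, "SYN2_SP", sGebv, sTbv[, cfg$indexTraits])
        archive$syn2sp[[as.character(cS2s)]] <- syn2sp
        availYear$syn2sp[as.character(cS2s)] <- year + 1L
        rm(syn2sp, sTbv, sGebv)
      }

      cyc$selSyn <- selSyn
      cyc$syn2Tbv <- NULL
      cycles[[cS2s]] <- cyc
    }

    ## -- terminal SYN3 (cycle year - 11) -------------------------------

    cS3 <- year - 11L
    if (cS3 >= 1L && cS3 <= cfg$nCycles && cfg$doSyn3 &&
        !is.null(cycles[[cS3]]$selSyn)) {
      syn2Sel <- archive$syn2plants[[as.character(cS3)]]
      invisible(intermateBlocks(syn2Sel, cfg$nSynSelected, cfg$synSize,
                                cfg$synSize, "SYN3",
                                unique(syn2Sel@lineage$family), cS3))
      cycles[[cS3]]$syn2 <- NULL
      cycles[[cS3]]$selSyn <- NULL
    }

    ## -- launch a new cycle --------------------------------------------

    if (year <= cfg$nCycles) {
      if (year <= cfg$independentCycles) {
        f1 <- makeF1Families(varieties, cfg$nF1Families, cfg$familySize,
                             cycle = year)
      } else {
        pool <- parentPool(cfg, year, archive, availYear)
        est <- if (cfg$genomic) getFit(year - 1L) else NULL
        f1 <- recruitAndCross(cfg, pool, est, panel, cycle = year)
      }
      tbv <- computeTbv(f1, arch)
      f1Mean[year, ] <- colMeans(tbv)
      grp <- rep(seq_len(cfg$nF1Families), each = cfg$familySize)
      famVar[year, ] <- apply(rowsum(tbv, grp) / cfg$familySize, 2, var)
      if (year == 1L) f1Cycle1Sd <- apply(tbv, 2, sd)
      cycles[[year]] <- list(f1 = f1)
      rm(f1, tbv)
    }
  }

  doneCycles <- which(!is.na(f1Mean[, 1]))
  gain <- geneticGain(f1Mean[doneCycles, , drop = FALSE], f1Cycle1Sd)
  av <- additiveVariance(famVar[doneCycles, , drop = FALSE])

  structure(list(
    config = cfg,
    gain = data.frame(
      cycle = rep(doneCycles, nTraits),
      trait = rep(traitNames, each = length(doneCycles)),
      meanTbv = as.vector(f1Mean[doneCycles, ]),
      deltaG = as.vector(gain)
    ),
    additiveVariance = data.frame(
      cycle = rep(doneCycles, nTraits),
      trait = rep(traitNames, each = length(doneCycles)),
      varFamilyMean = as.vector(famVar[doneCycles, ]),
      standardized = as.vector(av)
    ),
    accuracy = if (length(accRows) > 0) do.call(rbind, accRows)
               else data.frame(cycle = integer(0), year = integer(0),
                               stage = character(0), trait = character(0),
                               r = numeric(0)),
    referenceSize = if (length(refRows) > 0) do.call(rbind, refRows)
                    else data.frame(year = integer(0),
                                    nRecords = integer(0)),
    f1Cycle1Sd = f1Cycle1Sd
  ), class = "ScenarioResult")
}

#' @export
print.ScenarioResult <- function(x, ...) {
  cat("ScenarioResult '", x$config$name, "': ",
      length(unique(x$gain$cycle)), " cycles\n", sep = "")
  last <- max(x$gain$cycle)
  dg <- x$gain[x$gain$cycle == last, ]
  cat("  final-cycle gain (genetic SDs):",
      paste(dg$trait, signif(dg$deltaG, 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# Parent material available to a new cycle starting in `year`.
parentPool <- function(cfg, year, archive, availYear) {
  pools <- list()
  for (src in cfg$parentSources) {
    av <- availYear[[src]]
    ok <- names(av)[av <= year]
    pools <- c(pools, unname(archive[[src]][ok]))
  }
  if (length(pools) == 0L)
    stop("no parent material available in year ", year,
         " for scenario ", cfg$name)
  combineCohorts(pools)
}

# Select 2 * nF1Families parent slots from the pool (GS: the top plants by
# GEBV index, reused round-robin when the pool is smaller than the demand;
# phenotypic: uniform draws, since no cross-cycle comparison device
# exists) and cross them into F1 families.
recruitAndCross <- function(cfg, pool, est, panel, cycle) {
  n <- nInd(pool)
  fams <- pool@lineage$family
  if (cfg$genomic) {
    if (is.null(est))
      stop("no marker-effect estimate available for parent recruitment")
    gebv <- computeGebv(snpGenotypes(pool, panel), est)
    score <- selectionIndex(gebv, traits = seq_along(cfg$indexTraits),
                            weights = cfg$indexWeights)
    top <- selectTop(score, min(n, cfg$nParents), ids = pool@id)
    slots <- rep_len(top, cfg$nParents)
  } else {
    slots <- if (n >= cfg$nParents) sample.int(n, cfg$nParents)
             else sample.int(n, cfg$nParents, replace = TRUE)
  }
  pr <- pairParents(slots, fams)
  makeFamiliesFromParents(pool, pr$mo, pr$fa, cfg$familySize, cycle)
}
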