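# Shared fixtures, built in code and cached per test run. The "small"
# genome (2 chromosomes, 100 SNPs + 20 QTL each) keeps unit tests fast;
# the "mid" genome carries 700 QTL so trait-correlation tolerances match
# the full architecture.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

smallSpec <- function() {
  genomeSpec(nChromosomes = 2L, nLociPerChrom = 300L,
             nSnpPerChrom = 100L, nQtlPerChrom = 20L)
}

# Historical run + panel + 6 varieties of 40 on the small genome.
smallFounders <- function() {
  cached("smallFounders", {
    set.seed(420)
    spec <- smallSpec()
    hist <- simulateHistoricalPopulation(spec, 60L, rep(200L, 60L))
    panel <- buildLocusPanel(hist, spec)
    founders <- subsetLoci(hist, panel)
    varieties <- createInitialVarieties(founders, 6L, 40L)
    list(spec = spec, panel = panel, founders = founders,
         varieties = varieties)
  })
}

# Calibrated architecture on the small genome.
smallArch <- function() {
  cached("smallArch", {
    set.seed(421)
    f <- smallFounders()
    arch <- sampleQtlEffects(f$panel)
    calibrateArchitecture(f$varieties, arch, nPlots = 80L, familySize = 10L)
  })
}

# 700 pleiotropic QTL (2 chromosomes x 350) for trait-architecture tests.
midFounders <- function() {
  cached("midFounders", {
    set.seed(422)
    spec <- genomeSpec(nChromosomes = 2L, nLociPerChrom = 1000L,
                       nSnpPerChrom = 50L, nQtlPerChrom = 350L)
    hist <- simulateHistoricalPopulation(spec, 40L, rep(250L, 40L))
    panel <- buildLocusPanel(hist, spec)
    founders <- subsetLoci(hist, panel)
    list(spec = spec, panel = panel, founders = founders)
  })
}

# A cohort built from an explicit haplotype matrix (loci x 2n, 0/1),
# with a uniform map: used by the hand-computed oracles.
toyCohort <- function(haplo, nChrom = 1L, chromLengthCM = 100) {
  haplo <- as.matrix(haplo)
  L <- nrow(haplo)
  perChrom <- L %/% nChrom
  map <- new("LocusMap",
    chrom = rep(seq_len(nChrom), each = perChrom),
    posCM = rep(seq(1, chromLengthCM - 1, length.out = perChrom), nChrom),
    chromLengthCM = chromLengthCM
  )
  n <- ncol(haplo) %/% 2L
  new("Cohort",
    haplo = matrix(as.raw(haplo), nrow = L),
    id = paste0("T", seq_len(n)),
    lineage = data.frame(
      family = NA_character_, cycle = 0L, stage = "toy",
      mother = NA_character_, father = NA_character_,
      stringsAsFactors = FALSE
    )[rep(1L, n), , drop = FALSE],
    map = map
  )
}

# Toy panel over the same uniform map, explicit roles.
toyPanel <- function(nLoci, role = rep("SNP", nLoci), nChrom = 1L,
                     chromLengthCM = 100, founderFreq = rep(0.5, nLoci)) {
  perChrom <- nLoci %/% nChrom
  new("LocusPanel",
    chrom = rep(seq_len(nChrom), each = perChrom),
    posCM = rep(seq(1, chromLengthCM - 1, length.out = perChrom), nChrom),
    chromLengthCM = chromLengthCM,
    role = role,
    founderFreq = founderFreq,
    poolIndex = seq_len(nLoci)
  )
}

# One fully heterozygous parent (chromatids all-0 / all-1) on a dense
# 1000-locus grid covering essentially the whole 100 cM map, so allele
# switches along a gamete count crossovers without edge losses.
denseHetParent <- function() {
  L <- 1000L
  cohort <- toyCohort(cbind(rep(0L, L), rep(1L, L)))
  cohort@map <- new("LocusMap",
    chrom = rep(1L, L),
    posCM = seq(0.05, 99.95, length.out = L),
    chromLengthCM = 100
  )
  cohort
}

# Scaled-down scenario configuration sharing the real 12-year calendar.
smallScenario <- function(name, years = 16L, nCycles = 5L, ...) {
  scenarioConfig(name, years = years, nCycles = nCycles,
                 nF1Families = 20L, familySize = 10L, nSelF2 = 8L,
                 spFamilySize = 10L, nSPSelected = 32L, groupSize = 4L,
                 synSize = 10L, nSynSelected = 4L, plotSampleSize = 5L,
                 chain = list(nIter = 300L, burnIn = 100L), ...)
}
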