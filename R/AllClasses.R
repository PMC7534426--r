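#' Genome specification
#'
#' Parameters of the simulated ryegrass genome: chromosome number and map
#' length, the size of the oversampled locus pool used in the historical
#' population, the SNP/QTL panel sizes drawn from it, the recurrent mutation
#' rate, and the minor-allele-frequency floor for panel membership.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLengthCM genetic length of each chromosome in centimorgans.
#' @slot nSnpPerChrom number of panel SNPs per chromosome.
#' @slot nQtlPerChrom number of panel QTL per chromosome.
#' @slot nLociPerChrom size of the oversampled locus pool per chromosome
#'   simulated through the historical population.
#' @slot mutationRate per-locus, per-transmitted-gamete allele flip
#'   probability (historical phase only).
#' @slot mafMin minimum minor allele frequency for a locus to enter the
#'   SNP/QTL panel.
#' @export
setClass("GenomeSpec",
  representation(
    nChromosomes = "integer",
    chromLengthCM = "numeric",
    nSnpPerChrom = "integer",
    nQtlPerChrom = "integer",
    nLociPerChrom = "integer",
    mutationRate = "numeric",
    mafMin = "numeric"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- NULL
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  if (object@chromLengthCM <= 0) msg <- c(msg, "chromLengthCM must be > 0")
  if (object@mafMin <= 0 || object@mafMin >= 0.5)
    msg <- c(msg, "mafMin must lie in (0, 0.5)")
  if (object@mutationRate < 0 || object@mutationRate >= 1)
    msg <- c(msg, "mutationRate must lie in [0, 1)")
  if (object@nSnpPerChrom + object@nQtlPerChrom > object@nLociPerChrom)
    msg <- c(msg, "locus pool smaller than requested SNP + QTL panel")
  if (is.null(msg)) TRUE else msg
})

#' Construct a genome specification
#'
#' Defaults describe a 7-chromosome, 100 cM-per-chromosome diploid genome
#' with 1000 panel SNPs and 100 panel QTL per chromosome drawn from an
#' oversampled pool of 2500 simulated loci per chromosome, a recurrent
#' mutation rate of 2.5e-5, and a panel MAF floor of 0.05.
#'
#' @param nChromosomes,chromLengthCM,nSnpPerChrom,nQtlPerChrom,nLociPerChrom
#'   see the class slots.
#' @param mutationRate,mafMin see the class slots.
#' @return A [GenomeSpec-class] object.
#' @examples
#' genomeSpec()
#' genomeSpec(nChromosomes = 2, nLociPerChrom = 300, nSnpPerChrom = 100,
#'            nQtlPerChrom = 20)
#' @export
genomeSpec <- function(nChromosomes = 7L, chromLengthCM = 100,
                       nSnpPerChrom = 1000L, nQtlPerChrom = 100L,
                       nLociPerChrom = 2500L, mutationRate = 2.5e-5,
                       mafMin = 0.05) {
  new("GenomeSpec",
    nChromosomes = as.integer(nChromosomes),
    chromLengthCM = as.numeric(chromLengthCM),
    nSnpPerChrom = as.integer(nSnpPerChrom),
    nQtlPerChrom = as.integer(nQtlPerChrom),
    nLociPerChrom = as.integer(nLociPerChrom),
    mutationRate = as.numeric(mutationRate),
    mafMin = as.numeric(mafMin)
  )
}

#' Locus map
#'
#' Chromosome assignment and centimorgan position of every locus carried by
#' a cohort, sorted by position within chromosome. `LocusPanel` extends the
#' map with SNP/QTL roles, founder allele frequencies, and the indices of
#' the panel loci in the oversampled historical pool.
#'
#' @slot chrom integer chromosome index per locus.
#' @slot posCM map position in cM within chromosome, sorted.
#' @slot chromLengthCM chromosome length in cM (shared by all chromosomes).
#' @export
setClass("LocusMap",
  representation(
    chrom = "integer",
    posCM = "numeric",
    chromLengthCM = "numeric"
  )
)

setValidity("LocusMap", function(object) {
  msg <- NULL
  if (length(object@chrom) != length(object@posCM))
    msg <- c(msg, "chrom and posCM differ in length")
  if (any(object@posCM < 0) || any(object@posCM > object@chromLengthCM))
    msg <- c(msg, "positions outside [0, chromLengthCM]")
  if (is.unsorted(object@chrom))
    msg <- c(msg, "loci must be grouped by chromosome")
  for (c in unique(object@chrom)) {
    if (is.unsorted(object@posCM[object@chrom == c]))
      msg <- c(msg, sprintf("positions not sorted on chromosome %d", c))
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname LocusMap-class
#' @slot role character, "SNP" or "QTL" per locus.
#' @slot founderFreq allele-1 frequency of each locus in the final
#'   historical generation.
#' @slot poolIndex index of each panel locus in the oversampled pool the
#'   historical cohort was simulated on.
#' @export
setClass("LocusPanel",
  contains = "LocusMap",
  representation(
    role = "character",
    founderFreq = "numeric",
    poolIndex = "integer"
  )
)

setValidity("LocusPanel", function(object) {
  msg <- NULL
  n <- length(object@chrom)
  if (length(object@role) != n) msg <- c(msg, "role length mismatch")
  if (!all(object@role %in% c("SNP", "QTL")))
    msg <- c(msg, "role must be 'SNP' or 'QTL'")
  if (length(object@founderFreq) != n)
    msg <- c(msg, "founderFreq length mismatch")
  if (any(object@founderFreq <= 0) || any(object@founderFreq >= 1))
    msg <- c(msg, "panel loci must be polymorphic in the founder generation")
  if (is.null(msg)) TRUE else msg
})

#' Cohort of diploid individuals
#'
#' A set of diploid individuals stored as paired binary haplotypes over a
#' shared locus map. The haplotype matrix has loci in rows and haplotypes in
#' columns; individual `i` owns columns `2i - 1` and `2i`. Lineage records
#' the variety/family/group label, breeding cycle, and stage of every
#' individual.
#'
#' @slot haplo raw matrix of 0/1 alleles, loci x (2 x individuals).
#' @slot id character identifiers, one per individual.
#' @slot lineage data.frame with columns `family`, `cycle`, `stage`.
#' @slot map a [LocusMap-class] (usually a [LocusPanel-class]).
#' @export
setClass("Cohort",
  representation(
    haplo = "matrix",
    id = "character",
    lineage = "data.frame",
    map = "LocusMap"
  )
)

setValidity("Cohort", function(object) {
  msg <- NULL
  if (!is.raw(object@haplo)) msg <- c(msg, "haplo must be a raw matrix")
  if (ncol(object@haplo) %% 2L != 0L)
    msg <- c(msg, "haplo must have an even number of columns")
  n <- ncol(object@haplo) %/% 2L
  if (length(object@id) != n) msg <- c(msg, "one id per individual required")
  if (anyDuplicated(object@id)) msg <- c(msg, "duplicated individual ids")
  if (nrow(object@lineage) != n) msg <- c(msg, "lineage rows != individuals")
  if (!all(c("family", "cycle", "stage") %in% names(object@lineage)))
    msg <- c(msg, "lineage must have family, cycle, stage columns")
  if (nrow(object@haplo) != length(object@map@chrom))
    msg <- c(msg, "haplotype length != locus map length")
  if (is.null(msg)) TRUE else msg
})

#' Multi-trait QTL effect architecture
#'
#' Allele substitution effects of the pleiotropic QTL for all traits, the
#' trait correlation matrix the effects were sampled under, the calibrated
#' residual variances, and the target plot heritabilities.
#'
#' @slot alpha QTL x trait matrix of allele substitution effects.
#' @slot effectCorr trait x trait correlation of QTL effects.
#' @slot sigmaE2 per-trait residual (plot error) variance; `NA` until
#'   calibrated against target plot heritabilities.
#' @slot targetPlotH2 per-trait target plot heritability.
#' @slot qtlIndex indices of the QTL loci in the locus panel.
#' @export
setClass("TraitArchitecture",
  representation(
    alpha = "matrix",
    effectCorr = "matrix",
    sigmaE2 = "numeric",
    targetPlotH2 = "numeric",
    qtlIndex = "integer"
  )
)

setValidity("TraitArchitecture", function(object) {
  msg <- NULL
  k <- ncol(object@alpha)
  if (nrow(object@effectCorr) != k || ncol(object@effectCorr) != k)
    msg <- c(msg, "effectCorr dimension != trait count")
  if (any(abs(diag(object@effectCorr) - 1) > 1e-8))
    msg <- c(msg, "effectCorr must have unit diagonal")
  if (length(object@targetPlotH2) != k)
    msg <- c(msg, "one target plot h2 per trait required")
  if (any(object@targetPlotH2 <= 0) || any(object@targetPlotH2 > 1))
    msg <- c(msg, "target plot h2 must lie in (0, 1]")
  if (length(object@sigmaE2) != k)
    msg <- c(msg, "one sigmaE2 per trait required")
  if (any(!is.na(object@sigmaE2) & object@sigmaE2 < 0))
    msg <- c(msg, "sigmaE2 must be non-negative")
  if (nrow(object@alpha) != length(object@qtlIndex))
    msg <- c(msg, "alpha rows != number of QTL")
  if (is.null(msg)) TRUE else msg
})

#' Genomic prediction reference population
#'
#' Accumulating training set of plot records: one row per phenotyped plot
#' ("proxy individual") holding the mean allele dosage over panel SNPs and
#' the per-trait plot phenotype, plus provenance (stage, cycle, year).
#'
#' @slot X records x SNP matrix of mean allele dosages in [0, 2].
#' @slot y records x trait matrix of plot phenotypes.
#' @slot provenance data.frame with columns `id`, `stage`, `cycle`, `year`.
#' @export
setClass("ReferencePopulation",
  representation(
    X = "matrix",
    y = "matrix",
    provenance = "data.frame"
  )
)

setValidity("ReferencePopulation", function(object) {
  msg <- NULL
  if (nrow(object@X) != nrow(object@y))
    msg <- c(msg, "X and y row counts differ")
  if (nrow(object@provenance) != nrow(object@X))
    msg <- c(msg, "provenance rows != records")
  if (!all(c("id", "stage", "cycle", "year") %in% names(object@provenance)))
    msg <- c(msg, "provenance needs id, stage, cycle, year columns")
  if (anyDuplicated(object@provenance$id))
    msg <- c(msg, "duplicate record ids")
  if (nrow(object@X) > 0 && (min(object@X) < 0 || max(object@X) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (is.null(msg)) TRUE else msg
})

#' Posterior-mean marker effects
#'
#' Result of fitting Bayesian ridge regression per trait on a reference
#' population: posterior-mean intercepts, per-SNP effects, variance
#' components, and chain metadata.
#'
#' @slot mu per-trait posterior-mean intercept.
#' @slot effects SNP x trait matrix of posterior-mean allele substitution
#'   effects.
#' @slot varE,varB per-trait posterior-mean residual and marker-effect
#'   variances.
#' @slot centers SNP column means of the training dosages (applied again at
#'   prediction).
#' @slot chain list with `nIter`, `burnIn`, and the training snapshot size.
#' @export
setClass("MarkerEffectEstimate",
  representation(
    mu = "numeric",
    effects = "matrix",
    varE = "numeric",
    varB = "numeric",
    centers = "numeric",
    chain = "list"
  )
)

setValidity("MarkerEffectEstimate", function(object) {
  msg <- NULL
  k <- ncol(object@effects)
  if (length(object@mu) != k) msg <- c(msg, "one intercept per trait required")
  if (length(object@varE) != k || length(object@varB) != k)
    msg <- c(msg, "one variance component pair per trait required")
  if (length(object@centers) != nrow(object@effects))
    msg <- c(msg, "centers length != SNP count")
  if (any(!is.finite(object@effects)))
    msg <- c(msg, "non-finite marker effects")
  if (is.null(msg)) TRUE else msg
})
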