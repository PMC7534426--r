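#' Population-size schedule of the historical population
#'
#' Constant size for the first block of generations, then a linear decline
#' to the final size: the default reproduces 1000 generations at 2000
#' individuals followed by a gradual decrease from 2000 to 1000 over the
#' remaining 1000 generations, creating the initial linkage disequilibrium.
#'
#' @param nGenerations total number of generations.
#' @param sizeFrom constant population size of the first phase.
#' @param sizeTo final population size.
#' @param constantFor number of generations held at `sizeFrom`.
#' @return Integer vector of per-generation population sizes.
#' @examples
#' sched <- defaultSizeSchedule()
#' length(sched)     # 2000
#' range(sched)      # 1000 2000
#' @export
defaultSizeSchedule <- function(nGenerations = 2000L, sizeFrom = 2000L,
                                sizeTo = 1000L, constantFor = 1000L) {
  nGenerations <- as.integer(nGenerations)
  constantFor <- min(as.integer(constantFor), nGenerations)
  decline <- nGenerations - constantFor
  c(
    rep.int(as.integer(sizeFrom), constantFor),
    if (decline > 0)
      as.integer(round(seq(sizeFrom, sizeTo, length.out = decline)))
  )
}

# Uniform locus positions per chromosome, sorted; the shared map of the
# oversampled historical pool.
samplePoolMap <- function(spec) {
  pos <- unlist(lapply(seq_len(spec@nChromosomes), function(c)
    sort(runif(spec@nLociPerChrom, 0, spec@chromLengthCM))))
  new("LocusMap",
    chrom = rep(seq_len(spec@nChromosomes), each = spec@nLociPerChrom),
    posCM = pos,
    chromLengthCM = spec@chromLengthCM
  )
}

# 0-based chromosome offsets for the C++ kernels.
chromStarts <- function(map) {
  c(0L, cumsum(tabulate(map@chrom, nbins = max(map@chrom))))
}

#' Simulate the historical population
#'
#' Gene-drops an oversampled pool of bi-allelic loci through a long
#' historical population under random mating with replacement (monoecious,
#' selfing possible), Poisson(1) crossovers per chromosome per meiosis, and
#' recurrent symmetric mutation on every transmitted gamete. Initial allele
#' frequencies are drawn uniformly on (0, 1).
#'
#' @param spec a [GenomeSpec-class].
#' @param nGenerations number of generations to simulate.
#' @param sizeSchedule per-generation population sizes
#'   (length `nGenerations`); defaults to [defaultSizeSchedule()].
#' @param initialFreq optional per-locus initial allele frequencies
#'   (otherwise uniform on (0, 1)).
#' @return A [Cohort-class] of the final generation over the full locus
#'   pool, stage `"historical"`.
#' @seealso [buildLocusPanel()], [createInitialVarieties()]
#' @export
simulateHistoricalPopulation <- function(spec, nGenerations = 2000L,
                                         sizeSchedule =
                                           defaultSizeSchedule(nGenerations),
                                         initialFreq = NULL) {
  stopifnot(is(spec, "GenomeSpec"))
  nGenerations <- as.integer(nGenerations)
  if (length(sizeSchedule) != nGenerations)
    stop("sizeSchedule length (", length(sizeSchedule),
         ") != nGenerations (", nGenerations, ")")
  if (any(sizeSchedule < 1L)) stop("population sizes must be positive")

  map <- samplePoolMap(spec)
  L <- nLoci(map)
  n0 <- as.integer(sizeSchedule[1])
  if (is.null(initialFreq)) initialFreq <- runif(L)
  if (length(initialFreq) != L) stop("initialFreq length != locus count")

  founders <- matrix(
    as.raw(rbinom(L * 2L * n0, 1L, rep.int(initialFreq, 2L * n0))),
    nrow = L
  )
  final <- cpp_drop_generations(
    founders, as.integer(sizeSchedule), chromStarts(map), map@posCM,
    map@chromLengthCM, spec@mutationRate
  )
  n <- ncol(final) %/% 2L
  new("Cohort",
    haplo = final,
    id = paste0("H", seq_len(n)),
    lineage = data.frame(
      family = NA_character_, cycle = 0L, stage = "historical",
      mother = NA_character_, father = NA_character_,
      stringsAsFactors = FALSE
    )[rep(1L, n), , drop = FALSE],
    map = map
  )
}

#' Select the SNP/QTL locus panel
#'
#' Draws the requested numbers of SNPs and QTL per chromosome at random
#' from pool loci segregating with minor allele frequency above
#' `spec@mafMin` in the supplied (final historical) cohort. SNP and QTL
#' sets are disjoint; panel loci stay sorted by position.
#'
#' @param cohort the final historical [Cohort-class] over the full pool.
#' @param spec the [GenomeSpec-class] used to simulate it.
#' @return A [LocusPanel-class]; `poolIndex` maps panel loci back into the
#'   pool so the cohort can be reduced with [subsetLoci()].
#' @export
buildLocusPanel <- function(cohort, spec) {
  stopifnot(is(cohort, "Cohort"), is(spec, "GenomeSpec"))
  map <- cohort@map
  freq <- alleleFreq(cohort)
  maf <- pmin(freq, 1 - freq)
  need <- spec@nSnpPerChrom + spec@nQtlPerChrom

  picked <- integer(0)
  for (c in seq_len(spec@nChromosomes)) {
    onChrom <- which(map@chrom == c & maf > spec@mafMin)
    if (length(onChrom) < need)
      stop("chromosome ", c, ": only ", length(onChrom),
           " loci segregate with MAF > ", spec@mafMin, " but ", need,
           " are required; increase the locus pool or mutation rate")
    picked <- c(picked, sort(sample(onChrom, need)))
  }

  role <- character(length(picked))
  for (c in seq_len(spec@nChromosomes)) {
    block <- which(map@chrom[picked] == c)
    role[block] <- "SNP"
    role[sample(block, spec@nQtlPerChrom)] <- "QTL"
  }

  new("LocusPanel",
    chrom = map@chrom[picked],
    posCM = map@posCM[picked],
    chromLengthCM = map@chromLengthCM,
    role = role,
    founderFreq = freq[picked],
    poolIndex = picked
  )
}

#' Reduce a cohort to the panel loci
#'
#' @param cohort a [Cohort-class] over the locus pool the panel was drawn
#'   from.
#' @param panel a [LocusPanel-class] built by [buildLocusPanel()].
#' @return The cohort restricted to panel loci, with the panel as its map.
#' @export
subsetLoci <- function(cohort, panel) {
  stopifnot(is(cohort, "Cohort"), is(panel, "LocusPanel"))
  if (max(panel@poolIndex) > nLoci(cohort))
    stop("panel indexes loci beyond this cohort")
  new("Cohort",
    haplo = cohort@haplo[panel@poolIndex, , drop = FALSE],
    id = cohort@id,
    lineage = cohort@lineage,
    map = panel
  )
}

#' Create the initial varieties
#'
#' Draws random samples from the final historical generation and mates each
#' sample at random for one generation (distinct parent pairs, no selfing)
#' to form the initial varieties the breeding program starts from. Samples
#' are drawn without replacement within a variety but independently across
#' varieties.
#'
#' @param cohort founder [Cohort-class] (typically already reduced to the
#'   panel with [subsetLoci()]).
#' @param nVarieties number of varieties (default 20).
#' @param varietySize individuals per variety (default 200).
#' @return List of `nVarieties` [Cohort-class] objects, stage `"variety"`.
#' @export
createInitialVarieties <- function(cohort, nVarieties = 20L,
                                   varietySize = 200L) {
  stopifnot(is(cohort, "Cohort"))
  nVarieties <- as.integer(nVarieties)
  varietySize <- as.integer(varietySize)
  if (varietySize < 2L) stop("varietySize must be at least 2")
  n <- nInd(cohort)
  if (varietySize > n)
    stop("varietySize exceeds the founder cohort size")

  lapply(seq_len(nVarieties), function(v) {
    parents <- sample(n, varietySize)
    mo <- sample(parents, varietySize, replace = TRUE)
    fa <- sample(parents, varietySize, replace = TRUE)
    bad <- which(fa == mo)
    while (length(bad) > 0) {
      fa[bad] <- sample(parents, length(bad), replace = TRUE)
      bad <- bad[fa[bad] == mo[bad]]
    }
    hap <- cpp_mate(cohort@haplo, mo - 1L, fa - 1L,
                    chromStarts(cohort@map), cohort@map@posCM,
                    cohort@map@chromLengthCM)
    new("Cohort",
      haplo = hap,
      id = sprintf("V%d_%d", v, seq_len(varietySize)),
      lineage = data.frame(
        family = sprintf("V%d", v), cycle = 0L, stage = "variety",
        mother = cohort@id[mo], father = cohort@id[fa],
        stringsAsFactors = FALSE
      ),
      map = cohort@map
    )
  })
}

#' Simulate the founder material in one call
#'
#' Convenience wrapper chaining [simulateHistoricalPopulation()],
#' [buildLocusPanel()], [subsetLoci()] and [createInitialVarieties()].
#'
#' @inheritParams simulateHistoricalPopulation
#' @inheritParams createInitialVarieties
#' @param keepHistorical keep the full-pool historical cohort in the result
#'   (large; default drops it).
#' @return List with elements `panel` ([LocusPanel-class]), `founders`
#'   (final historical cohort over panel loci), and `varieties` (list of
#'   variety cohorts).
#' @export
simulateFounders <- function(spec = genomeSpec(), nGenerations = 2000L,
                             sizeSchedule = defaultSizeSchedule(nGenerations),
                             nVarieties = 20L, varietySize = 200L,
                             keepHistorical = FALSE) {
  hist <- simulateHistoricalPopulation(spec, nGenerations, sizeSchedule)
  panel <- buildLocusPanel(hist, spec)
  founders <- subsetLoci(hist, panel)
  varieties <- createInitialVarieties(founders, nVarieties, varietySize)
  out <- list(panel = panel, founders = founders, varieties = varieties)
  if (keepHistorical) out$historical <- hist
  out
}

#' Export a cohort as VCF
#'
#' Writes a minimal VCFv4.2 file with one contig per chromosome and
#' unphased diploid GT fields. Map positions are scaled to integer base
#' pairs at 1 cM = 1,000,000 bp.
#'
#' @param cohort a [Cohort-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportVCF <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  map <- cohort@map
  n <- nInd(cohort)
  L <- nLoci(cohort)
  bp <- pmax(1L, as.integer(round(map@posCM * 1e6)))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ryegrassGS",
    sprintf("##contig=<ID=chr%d,length=%d>", unique(map@chrom),
            as.integer(map@chromLengthCM * 1e6) + 1L),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort@id), collapse = "\t")
  ), con)

  h <- matrix(as.integer(cohort@haplo), nrow = L)
  gt <- matrix(paste(h[, 2L * seq_len(n) - 1L, drop = FALSE],
                     h[, 2L * seq_len(n), drop = FALSE], sep = "/"),
               nrow = L)
  rows <- paste(
    paste0("chr", map@chrom), bp, sprintf("locus%d", seq_len(L)),
    "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(rows, con)
  invisible(path)
}

#' Export genotype dosages as CSV
#'
#' Individuals in rows, loci in columns (0/1/2 dosages of allele 1).
#'
#' @inheritParams exportVCF
#' @export
exportDosageCSV <- function(cohort, path) {
  d <- dosage(cohort)
  colnames(d) <- sprintf("locus%d", seq_len(ncol(d)))
  write.csv(d, path, row.names = TRUE)
  invisible(path)
}
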