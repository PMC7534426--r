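#' Accessors for simulation containers
#'
#' Small generic family giving read access to the core containers without
#' touching slots: individual and locus counts, haplotypes, genotype
#' dosages, allele frequencies, lineage, and locus-panel bookkeeping.
#'
#' @param x a [Cohort-class], [LocusMap-class]/[LocusPanel-class], or
#'   [ReferencePopulation-class] object as appropriate.
#' @param loci optional integer indices restricting dosage/frequency
#'   extraction to a subset of loci.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("dosage", function(x, loci = NULL) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x, loci = NULL) standardGeneric("alleleFreq"))

#' @rdname accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @rdname accessors
#' @export
setGeneric("locusMap", function(x) standardGeneric("locusMap"))

#' @rdname accessors
#' @export
setGeneric("snpIndices", function(x) standardGeneric("snpIndices"))

#' @rdname accessors
#' @export
setGeneric("qtlIndices", function(x) standardGeneric("qtlIndices"))

#' @rdname accessors
#' @export
setMethod("nInd", "Cohort", function(x) ncol(x@haplo) %/% 2L)

#' @rdname accessors
#' @export
setMethod("nLoci", "Cohort", function(x) nrow(x@haplo))

#' @rdname accessors
#' @export
setMethod("nLoci", "LocusMap", function(x) length(x@chrom))

#' @rdname accessors
#' @export
setMethod("haplotypes", "Cohort", function(x) x@haplo)

#' @rdname accessors
#' @export
setMethod("dosage", "Cohort", function(x, loci = NULL) {
  h <- if (is.null(loci)) x@haplo else x@haplo[loci, , drop = FALSE]
  d <- cpp_dosage(h)
  rownames(d) <- x@id
  d
})

#' @rdname accessors
#' @export
setMethod("alleleFreq", "Cohort", function(x, loci = NULL) {
  h <- if (is.null(loci)) x@haplo else x@haplo[loci, , drop = FALSE]
  cpp_allele_freq(h)
})

#' @rdname accessors
#' @export
setMethod("lineage", "Cohort", function(x) x@lineage)

#' @rdname accessors
#' @export
setMethod("locusMap", "Cohort", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("snpIndices", "LocusPanel", function(x) which(x@role == "SNP"))

#' @rdname accessors
#' @export
setMethod("qtlIndices", "LocusPanel", function(x) which(x@role == "QTL"))

#' @rdname accessors
#' @param i integer, logical, or character (id) index of individuals.
#' @param j,drop,... ignored; present for generic compatibility.
#' @export
setMethod("[", "Cohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  i <- seq_len(nInd(x))[i]
  if (anyNA(i)) stop("unknown individual selected")
  cols <- as.vector(rbind(2L * i - 1L, 2L * i))
  new("Cohort",
    haplo = x@haplo[, cols, drop = FALSE],
    id = x@id[i],
    lineage = x@lineage[i, , drop = FALSE],
    map = x@map
  )
})

#' Pool several cohorts over the same locus map
#'
#' @param ... [Cohort-class] objects, or a single list of them.
#' @return A single [Cohort-class]; ids must be unique across inputs.
#' @export
combineCohorts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "Cohort"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  if (length(xs) == 1L) return(xs[[1]])
  nl <- vapply(xs, nLoci, integer(1))
  if (length(unique(nl)) != 1L) stop("cohorts use different locus maps")
  new("Cohort",
    haplo = do.call(cbind, lapply(xs, haplotypes)),
    id = unlist(lapply(xs, function(x) x@id), use.names = FALSE),
    lineage = do.call(rbind, lapply(xs, lineage)),
    map = xs[[1]]@map
  )
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@nChromosomes, "chromosomes x",
      object@chromLengthCM, "cM\n")
  cat("  panel/chrom:", object@nSnpPerChrom, "SNPs +",
      object@nQtlPerChrom, "QTL from a pool of", object@nLociPerChrom, "\n")
  cat("  mutation rate:", object@mutationRate, " MAF floor:",
      object@mafMin, "\n")
})

setMethod("show", "LocusMap", function(object) {
  cat(class(object), "with", length(object@chrom), "loci on",
      length(unique(object@chrom)), "chromosomes\n")
  if (is(object, "LocusPanel"))
    cat("  roles:", sum(object@role == "SNP"), "SNPs,",
        sum(object@role == "QTL"), "QTL\n")
})

setMethod("show", "Cohort", function(object) {
  st <- unique(object@lineage$stage)
  cat("Cohort of", nInd(object), "individuals over", nLoci(object),
      "loci\n")
  cat("  stage:", paste(head(st, 3), collapse = ", "),
      if (length(st) > 3) "..." else "", "\n")
})

setMethod("show", "ReferencePopulation", function(object) {
  cat("ReferencePopulation:", nrow(object@X), "plot records x",
      ncol(object@X), "SNPs\n")
  if (nrow(object@provenance) > 0) {
    tab <- table(object@provenance$stage)
    cat("  stages:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "MarkerEffectEstimate", function(object) {
  cat("MarkerEffectEstimate:", nrow(object@effects), "SNPs x",
      ncol(object@effects), "traits (",
      object@chain$nIter, "iterations,", object@chain$burnIn, "burn-in )\n")
})

setMethod("show", "TraitArchitecture", function(object) {
  cat("TraitArchitecture:", nrow(object@alpha), "pleiotropic QTL x",
      ncol(object@alpha), "traits\n")
  cat("  target plot h2:", paste(object@targetPlotH2, collapse = ", "), "\n")
  cat("  sigmaE2:",
      if (all(is.na(object@sigmaE2))) "uncalibrated"
      else paste(signif(object@sigmaE2, 3), collapse = ", "), "\n")
})
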