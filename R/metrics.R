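#' Cumulative genetic gain
#'
#' Gain of cycle i, per trait, in genetic standard deviation units:
#' the difference between the mean F1 TBV of cycle i and of cycle 1,
#' divided by the standard deviation of cycle-1 F1 TBVs. Cycle 1 is 0 by
#' definition.
#'
#' @param f1MeanTbv cycles x traits matrix of mean F1 TBVs.
#' @param f1Cycle1Sd per-trait standard deviation of individual F1 TBVs in
#'   cycle 1.
#' @return cycles x traits matrix of cumulative gains.
#' @export
geneticGain <- function(f1MeanTbv, f1Cycle1Sd) {
  f1MeanTbv <- as.matrix(f1MeanTbv)
  if (any(f1Cycle1Sd <= 0)) stop("zero cycle-1 TBV standard deviation")
  sweep(sweep(f1MeanTbv, 2, f1MeanTbv[1, ]), 2, f1Cycle1Sd, "/")
}

#' Selection accuracy
#'
#' Pearson correlation between estimated values (GEBVs or plot phenotypes)
#' and true breeding values over a candidate set.
#'
#' @param estimates,tbvs numeric vectors (one trait) or matrices
#'   (candidates x traits, correlated column-wise).
#' @return Correlation per trait; `NA` with a warning when a variance is
#'   degenerate.
#' @export
selectionAccuracy <- function(estimates, tbvs) {
  e <- as.matrix(estimates)
  t <- as.matrix(tbvs)
  if (!all(dim(e) == dim(t))) stop("dimension mismatch")
  if (nrow(e) < 3L) stop("at least 3 candidate pairs required")
  vapply(seq_len(ncol(e)), function(j) {
    if (sd(e[, j]) == 0 || sd(t[, j]) == 0) {
      warning("degenerate variance; accuracy undefined")
      return(NA_real_)
    }
    cor(e[, j], t[, j])
  }, numeric(1))
}

#' Additive genetic variance trajectory
#'
#' Per cycle, the variance over the F1 family mean TBVs, standardized by
#' the cycle-1 value (so cycle 1 is 1 by definition).
#'
#' @param familyMeans list (one element per cycle) of families x traits
#'   matrices of family mean TBVs, or a cycles x traits matrix of
#'   already-computed variances.
#' @return cycles x traits matrix of standardized additive variances.
#' @export
additiveVariance <- function(familyMeans) {
  v <- if (is.list(familyMeans)) {
    k <- ncol(as.matrix(familyMeans[[1]]))
    vv <- vapply(familyMeans, function(m) {
      m <- as.matrix(m)
      if (nrow(m) < 2L) stop("at least 2 families per cycle required")
      apply(m, 2, var)
    }, numeric(k))
    if (k == 1L) matrix(vv, ncol = 1L) else t(vv)
  } else {
    as.matrix(familyMeans)
  }
  sweep(v, 2, v[1, ], "/")
}

#' Observed heterozygosity
#'
#' Mean fraction of heterozygous genotypes over individuals and loci
#' (panel SNPs by default when the cohort's map is a panel).
#'
#' @param cohort a [Cohort-class].
#' @param loci locus indices; defaults to the panel SNPs when available,
#'   otherwise all loci.
#' @return A proportion in [0, 1].
#' @export
observedHeterozygosity <- function(cohort, loci = NULL) {
  stopifnot(is(cohort, "Cohort"))
  if (is.null(loci) && is(cohort@map, "LocusPanel"))
    loci <- snpIndices(cohort@map)
  h <- if (is.null(loci)) cohort@haplo
       else cohort@haplo[loci, , drop = FALSE]
  cpp_het(h)
}

# Internal: r2 between consecutive columns of a dosage matrix.
adjacentPairR2 <- function(X) {
  n <- nrow(X)
  if (ncol(X) < 2L) return(numeric(0))
  m <- colMeans(X)
  ctr <- sweep(X, 2, m)
  v <- colSums(ctr^2)
  x1 <- seq_len(ncol(X) - 1L)
  x2 <- x1 + 1L
  cv <- colSums(ctr[, x1, drop = FALSE] * ctr[, x2, drop = FALSE])
  ok <- v[x1] > 0 & v[x2] > 0
  (cv[ok]^2) / (v[x1][ok] * v[x2][ok])
}

#' Mean r2 of adjacent SNPs in the initial varieties
#'
#' Within each variety, SNPs with within-variety MAF above `mafMin` are
#' retained (LD is near-undetectable when either locus has an extreme
#' frequency) and r2 is the squared Pearson correlation of genotype
#' dosages between consecutive retained SNPs on the same chromosome; the
#' per-variety means are averaged.
#'
#' @param varieties list of variety [Cohort-class] objects over a
#'   [LocusPanel-class].
#' @param mafMin within-variety MAF filter (default 0.05).
#' @return Mean adjacent-SNP r2 across varieties.
#' @export
adjacentSnpR2 <- function(varieties, mafMin = 0.05) {
  if (is(varieties, "Cohort")) varieties <- list(varieties)
  perVariety <- vapply(varieties, function(v) {
    panel <- v@map
    stopifnot(is(panel, "LocusPanel"))
    snps <- snpIndices(panel)
    f <- alleleFreq(v, snps)
    keep <- pmin(f, 1 - f) > mafMin
    idx <- snps[keep]
    chrom <- panel@chrom[idx]
    D <- dosage(v, idx)
    r2 <- unlist(lapply(unique(chrom), function(c)
      adjacentPairR2(D[, chrom == c, drop = FALSE])))
    mean(r2)
  }, numeric(1))
  mean(perVariety)
}

#' Linkage disequilibrium decay
#'
#' Within each variety, pairwise r2 (squared Pearson correlation of
#' genotype dosages) is computed for all same-chromosome SNP pairs up to
#' `maxCM` apart, after the within-variety MAF filter; pairs are binned by
#' distance in `binCM` intervals starting at 0 and the per-bin means are
#' averaged over varieties. Empty bins are `NA`.
#'
#' @inheritParams adjacentSnpR2
#' @param maxCM largest pair distance considered (default 20 cM).
#' @param binCM bin width (default 1 cM).
#' @return data.frame with `binStartCM`, `binMidCM`, `meanR2`, `nPairs`.
#' @export
ldDecay <- function(varieties, mafMin = 0.05, maxCM = 20, binCM = 1) {
  if (is(varieties, "Cohort")) varieties <- list(varieties)
  nBins <- as.integer(ceiling(maxCM / binCM))
  sums <- counts <- numeric(nBins)

  for (v in varieties) {
    panel <- v@map
    stopifnot(is(panel, "LocusPanel"))
    snps <- snpIndices(panel)
    f <- alleleFreq(v, snps)
    keep <- pmin(f, 1 - f) > mafMin
    idx <- snps[keep]
    for (c in unique(panel@chrom[idx])) {
      ii <- idx[panel@chrom[idx] == c]
      if (length(ii) < 2L) next
      pos <- panel@posCM[ii]
      D <- dosage(v, ii)
      r2 <- suppressWarnings(cor(D)^2)
      dmat <- abs(outer(pos, pos, "-"))
      ut <- upper.tri(dmat)
      sel <- ut & dmat <= maxCM
      bin <- pmin(nBins, floor(dmat[sel] / binCM) + 1L)
      val <- r2[sel]
      ok <- is.finite(val)
      sums <- sums + vapply(seq_len(nBins), function(b)
        sum(val[ok & bin == b]), numeric(1))
      counts <- counts + vapply(seq_len(nBins), function(b)
        sum(ok & bin == b), numeric(1))
    }
  }
  data.frame(
    binStartCM = (seq_len(nBins) - 1L) * binCM,
    binMidCM = (seq_len(nBins) - 0.5) * binCM,
    meanR2 = ifelse(counts > 0, sums / counts, NA_real_),
    nPairs = counts
  )
}

#' Expected r2 under drift-recombination balance
#'
#' Sved-type expectation `1 / (1 + k * Ne * c)` for the equilibrium r2 of
#' a pair of loci at recombination fraction `c` in a population of
#' effective size `Ne`; `k = 4` by default.
#'
#' @param Ne effective population size.
#' @param c recombination fraction in [0, 0.5].
#' @param k constant of the expectation (default 4).
#' @return Expected r2.
#' @export
expectedR2Sved <- function(Ne, c, k = 4) {
  if (any(Ne <= 0)) stop("Ne must be positive")
  if (any(c < 0 | c > 0.5)) stop("recombination fraction outside [0, 0.5]")
  1 / (1 + k * Ne * c)
}

#' Haldane map function
#'
#' Recombination fraction for a map distance in cM (no interference):
#' `c = (1 - exp(-2 d)) / 2` with `d` in Morgans.
#'
#' @param cM map distance in centimorgans.
#' @return Recombination fraction.
#' @export
haldane <- function(cM) 0.5 * (1 - exp(-2 * cM / 100))
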