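#' Mean allele dosage of a plot
#'
#' Genotypes a family pool the way a plot is genotyped in practice: a
#' subset of plants is sampled without replacement and, per panel SNP, the
#' dosage is twice the frequency of the counted allele among the sampled
#' plants, a real number in [0, 2] (a frequency of 0.7 gives dosage 1.4).
#'
#' @param members [Cohort-class] of the plot's plants.
#' @param panel the [LocusPanel-class] (dosages are over its SNP loci).
#' @param nSample plants sampled per plot (default 20).
#' @return Numeric dosage vector, one entry per panel SNP.
#' @export
plotDosage <- function(members, panel, nSample = 20L) {
  stopifnot(is(members, "Cohort"), is(panel, "LocusPanel"))
  n <- nInd(members)
  nSample <- as.integer(nSample)
  if (n < nSample)
    stop("plot has ", n, " plants; cannot sample ", nSample)
  keep <- sort(sample(n, nSample))
  sub <- members[keep]
  2 * alleleFreq(sub, snpIndices(panel))
}

#' Empty reference population
#'
#' @param nSnp number of panel SNPs.
#' @param nTraits number of phenotyped traits (default 4).
#' @return A [ReferencePopulation-class] with zero records.
#' @export
newReferencePopulation <- function(nSnp, nTraits = 4L) {
  new("ReferencePopulation",
    X = matrix(numeric(0), 0L, nSnp),
    y = matrix(numeric(0), 0L, nTraits),
    provenance = data.frame(
      id = character(0), stage = character(0), cycle = integer(0),
      year = integer(0), stringsAsFactors = FALSE
    )
  )
}

#' Append plot records to the reference population
#'
#' The reference grows monotonically as new F2 families and SYN2 groups are
#' phenotyped and genotyped; records are never removed and duplicate ids
#' are rejected.
#'
#' @param ref a [ReferencePopulation-class].
#' @param X new records x SNP dosage matrix.
#' @param y new records x trait phenotype matrix.
#' @param id record identifiers.
#' @param stage `"F2"` or `"SYN2"`.
#' @param cycle,year provenance of the new records.
#' @return The grown [ReferencePopulation-class].
#' @export
updateReference <- function(ref, X, y, id, stage, cycle, year) {
  stopifnot(is(ref, "ReferencePopulation"))
  X <- as.matrix(X)
  y <- as.matrix(y)
  if (nrow(X) == 0L) return(ref)
  if (ncol(ref@X) > 0L && ncol(X) != ncol(ref@X))
    stop("SNP count of new records differs from the reference")
  if (any(id %in% ref@provenance$id)) stop("duplicate record ids")
  prov <- data.frame(
    id = id, stage = rep_len(stage, nrow(X)),
    cycle = rep_len(as.integer(cycle), nrow(X)),
    year = rep_len(as.integer(year), nrow(X)), stringsAsFactors = FALSE
  )
  new("ReferencePopulation",
    X = rbind(ref@X, X),
    y = rbind(ref@y, y),
    provenance = rbind(ref@provenance, prov)
  )
}

#' Filter reference records by phenotyping year
#'
#' @param ref a [ReferencePopulation-class].
#' @param maxYear keep records phenotyped in years `<= maxYear`.
#' @return The filtered [ReferencePopulation-class].
#' @export
referenceAsOf <- function(ref, maxYear) {
  keep <- ref@provenance$year <= maxYear
  new("ReferencePopulation",
    X = ref@X[keep, , drop = FALSE],
    y = ref@y[keep, , drop = FALSE],
    provenance = ref@provenance[keep, , drop = FALSE]
  )
}

#' Gibbs chain profiles
#'
#' `"full"` runs 50,000 iterations with 10,000 burn-in; `"fast"` runs
#' 5,000 with 1,000 burn-in for desk-scale work.
#'
#' @param profile `"full"`, `"fast"`, or a list with `nIter` and `burnIn`.
#' @return List with `nIter` and `burnIn`.
#' @export
chainProfile <- function(profile = c("fast", "full")) {
  if (is.list(profile)) {
    stopifnot(all(c("nIter", "burnIn") %in% names(profile)))
    return(profile[c("nIter", "burnIn")])
  }
  switch(match.arg(profile),
    full = list(nIter = 50000L, burnIn = 10000L),
    fast = list(nIter = 5000L, burnIn = 1000L)
  )
}

#' Fit Bayesian ridge regression by Gibbs sampling
#'
#' Per-trait univariate model `y = mu + X a + e` with a common Gaussian
#' prior on all marker effects and scaled-inverse-chi-square priors
#' (5 degrees of freedom) on both variance components, their scales set
#' from the sample variance of the phenotypes: the residual-variance prior
#' mode is half `var(y)` and the marker-variance prior mode is half
#' `var(y)` divided by the summed dosage-column variances. Columns of `X`
#' are centered by their training means; the same centers are applied at
#' prediction by [computeGebv()]. Single-site updates with residual
#' updating; posterior means over the post-burn-in samples are returned.
#'
#' @param ref a [ReferencePopulation-class] with at least 2 records.
#' @param traits trait columns of `ref@y` to fit (default `c(1, 3, 4)`).
#' @param chain a [chainProfile()] list.
#' @param df prior degrees of freedom for both variance components.
#' @param priorR2 proportion of phenotypic variance assigned to markers by
#'   the prior-scale rule (default 0.5).
#' @param fixVarE,fixVarB optional fixed values for the variance
#'   components (degenerate priors), used for closed-form cross-checks.
#' @return A [MarkerEffectEstimate-class] covering the requested traits.
#' @export
fitBrr <- function(ref, traits = c(1L, 3L, 4L), chain = chainProfile("fast"),
                   df = 5, priorR2 = 0.5, fixVarE = NULL, fixVarB = NULL) {
  stopifnot(is(ref, "ReferencePopulation"))
  n <- nrow(ref@X)
  if (n < 2L) stop("reference population needs at least 2 records")
  if (any(!is.finite(ref@y[, traits]))) stop("non-finite phenotypes")
  chain <- chainProfile(chain)

  centers <- colMeans(ref@X)
  Xc <- sweep(ref@X, 2, centers)
  sumVx <- sum(apply(Xc, 2, var))
  p <- ncol(Xc)

  effects <- matrix(0, p, length(traits))
  mu <- varE <- varB <- numeric(length(traits))
  for (t in seq_along(traits)) {
    y <- ref@y[, traits[t]]
    vy <- var(y)
    if (vy <= 0) {
      warning("zero-variance phenotype for trait ", traits[t],
              "; returning zero effects")
      mu[t] <- mean(y)
      next
    }
    # prior scales: mode S/(df + 2) matches the priorR2 split of var(y)
    Se <- (1 - priorR2) * vy * (df + 2)
    Sm <- priorR2 * vy / max(sumVx, .Machine$double.eps) * (df + 2)
    fit <- cpp_brr_gibbs(Xc, y, chain$nIter, chain$burnIn, df, Se, Sm,
                         if (is.null(fixVarE)) -1 else fixVarE,
                         if (is.null(fixVarB)) -1 else fixVarB)
    mu[t] <- fit$mu
    effects[, t] <- fit$effects
    varE[t] <- fit$varE
    varB[t] <- fit$varB
  }
  colnames(effects) <- colnames(ref@y)[traits]
  new("MarkerEffectEstimate",
    mu = mu, effects = effects, varE = varE, varB = varB,
    centers = centers,
    chain = c(chain, list(nRecords = n, traits = traits))
  )
}

#' Genomic estimated breeding values
#'
#' GEBV of a candidate is the sum over SNPs of its allele count (0/1/2 for
#' single plants, mean dosage in [0, 2] for plots) times the posterior-mean
#' substitution effect. Training centers are subtracted first; the
#' intercept is omitted, leaving rankings unchanged.
#'
#' @param x candidates x SNP matrix (or a single dosage vector).
#' @param est a [MarkerEffectEstimate-class].
#' @return candidates x traits matrix of GEBVs.
#' @export
computeGebv <- function(x, est) {
  stopifnot(is(est, "MarkerEffectEstimate"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(est@effects))
    stop("candidate genotypes have ", ncol(x), " SNPs; estimate has ",
         nrow(est@effects))
  sweep(x, 2, est@centers) %*% est@effects
}

#' Single-plant SNP genotypes
#'
#' Observed 0/1/2 genotypes of individually genotyped plants over the
#' panel SNPs, as used for single-plant GEBVs.
#'
#' @param cohort a [Cohort-class].
#' @param panel the [LocusPanel-class].
#' @return individuals x SNP integer matrix.
#' @export
snpGenotypes <- function(cohort, panel) {
  dosage(cohort, snpIndices(panel))
}

#' Write marker-effect estimates as CSV
#'
#' @param est a [MarkerEffectEstimate-class].
#' @param path output file path.
#' @export
exportEffectsCSV <- function(est, path) {
  df <- data.frame(snp = seq_len(nrow(est@effects)), est@effects)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
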