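#' Default trait correlation structure
#'
#' Four traits; QTL effects of traits 3 and 4 are correlated at 0.7, all
#' other pairs are uncorrelated, so the realized genetic correlation
#' between traits 3 and 4 is 0.7.
#'
#' @param rho34 effect correlation between traits 3 and 4.
#' @return 4 x 4 correlation matrix.
#' @export
defaultEffectCorr <- function(rho34 = 0.7) {
  m <- diag(4)
  m[3, 4] <- m[4, 3] <- rho34
  dimnames(m) <- list(paste0("trait", 1:4), paste0("trait", 1:4))
  m
}

#' Sample pleiotropic QTL effects
#'
#' Draws allele substitution effects for every panel QTL from a zero-mean
#' multivariate normal with unit per-trait variance and the given effect
#' correlation; all QTL are shared (pleiotropic) across traits. Residual
#' variances are left uncalibrated (`NA`) until [calibrateToPlotH2()].
#'
#' @param panel a [LocusPanel-class].
#' @param effectCorr trait correlation matrix of the effects
#'   (default [defaultEffectCorr()]).
#' @param targetPlotH2 per-trait target plot heritabilities
#'   (default `c(0.3, 0.6, 0.4, 0.2)`).
#' @return A [TraitArchitecture-class].
#' @export
sampleQtlEffects <- function(panel, effectCorr = defaultEffectCorr(),
                             targetPlotH2 = c(0.3, 0.6, 0.4, 0.2)) {
  stopifnot(is(panel, "LocusPanel"))
  k <- ncol(effectCorr)
  if (length(targetPlotH2) != k)
    stop("targetPlotH2 length != trait count")
  ev <- eigen(effectCorr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("effectCorr is not positive semi-definite")

  qtl <- which(panel@role == "QTL")
  nQtl <- length(qtl)
  Z <- matrix(rnorm(nQtl * k), nQtl, k)
  R <- chol(effectCorr + diag(1e-10, k))
  alpha <- Z %*% R
  colnames(alpha) <- colnames(effectCorr)

  new("TraitArchitecture",
    alpha = alpha,
    effectCorr = effectCorr,
    sigmaE2 = rep(NA_real_, k),
    targetPlotH2 = as.numeric(targetPlotH2),
    qtlIndex = qtl
  )
}

#' True breeding values
#'
#' TBV of individual i for a trait is the sum over QTL of genotype dosage
#' (0/1/2) times the allele substitution effect; panel SNPs carry no
#' effect.
#'
#' @param cohort a [Cohort-class] over the locus panel.
#' @param arch a [TraitArchitecture-class] sampled on the same panel.
#' @return individuals x traits matrix of TBVs.
#' @export
computeTbv <- function(cohort, arch) {
  stopifnot(is(cohort, "Cohort"), is(arch, "TraitArchitecture"))
  if (max(arch@qtlIndex) > nLoci(cohort))
    stop("architecture QTL indices exceed cohort locus count")
  G <- dosage(cohort, arch@qtlIndex)
  tbv <- G %*% arch@alpha
  rownames(tbv) <- cohort@id
  tbv
}

#' Plot-level true breeding value
#'
#' The TBV of a plot is the mean TBV of its member plants, per trait.
#'
#' @param tbv individuals x traits TBV matrix of the plot members.
#' @return Per-trait plot TBV (numeric vector).
#' @export
plotTbv <- function(tbv) colMeans(tbv)

#' Calibrate residual variances to target plot heritabilities
#'
#' Plot heritability is the squared correlation between plot mean TBV and
#' plot phenotype; under the additive model it equals
#' `var(plotTbv) / (var(plotTbv) + sigmaE2)`. Given a calibration set of
#' plot TBVs the residual variance solving the target exactly is
#' `sigmaE2 = var(plotTbv) * (1 - h2) / h2`, applied per trait. Effect
#' scales (and therefore all effect correlations) are untouched.
#'
#' @param plotTbvs plots x traits matrix of plot mean TBVs from a
#'   calibration set of plots (at least 2 plots).
#' @param arch the [TraitArchitecture-class] to calibrate.
#' @return The architecture with `sigmaE2` filled in.
#' @export
calibrateToPlotH2 <- function(plotTbvs, arch) {
  stopifnot(is(arch, "TraitArchitecture"))
  plotTbvs <- as.matrix(plotTbvs)
  if (nrow(plotTbvs) < 2L) stop("calibration set needs at least 2 plots")
  v <- apply(plotTbvs, 2, var)
  if (any(v <= 0)) stop("zero variance of plot TBV in the calibration set")
  h2 <- arch@targetPlotH2
  arch@sigmaE2 <- v * (1 - h2) / h2
  arch
}

#' Plot phenotypes
#'
#' Adds an independent normal deviate with the calibrated residual
#' variance to each plot TBV, per trait and plot.
#'
#' @param plotTbvs plots x traits matrix (or per-trait vector for a single
#'   plot) of plot mean TBVs.
#' @param arch a calibrated [TraitArchitecture-class].
#' @return Matrix of plot phenotypes, same shape as `plotTbvs`.
#' @export
plotPhenotype <- function(plotTbvs, arch) {
  stopifnot(is(arch, "TraitArchitecture"))
  if (any(is.na(arch@sigmaE2)))
    stop("architecture is not calibrated; run calibrateToPlotH2() first")
  m <- if (is.matrix(plotTbvs)) plotTbvs else matrix(plotTbvs, nrow = 1)
  k <- ncol(m)
  noise <- matrix(rnorm(nrow(m) * k), nrow(m), k) *
    rep(sqrt(arch@sigmaE2), each = nrow(m))
  out <- m + noise
  if (!is.matrix(plotTbvs)) out <- drop(out)
  out
}

#' Single-plant phenotypes
#'
#' Individual-plant phenotype for one trait: TBV plus a normal deviate with
#' that trait's calibrated residual variance. Used for the heading-date
#' grouping of polycross parents (trait 2), which is never selected on.
#'
#' @param tbv per-individual TBV vector for the trait (or individuals x
#'   traits matrix, subset by `trait`).
#' @param arch a calibrated [TraitArchitecture-class].
#' @param trait trait index (default 2, heading date).
#' @return Numeric vector of single-plant phenotypes.
#' @export
singlePlantPhenotype <- function(tbv, arch, trait = 2L) {
  stopifnot(is(arch, "TraitArchitecture"))
  s2 <- arch@sigmaE2[trait]
  if (is.na(s2)) stop("architecture is not calibrated for trait ", trait)
  if (is.matrix(tbv)) tbv <- tbv[, trait]
  tbv + rnorm(length(tbv), 0, sqrt(s2))
}

#' Write the trait architecture as CSV
#'
#' One row per QTL: panel index, chromosome, position, and the allele
#' substitution effect per trait.
#'
#' @param arch a [TraitArchitecture-class].
#' @param panel the [LocusPanel-class] it was sampled on.
#' @param path output file path.
#' @export
exportArchitectureCSV <- function(arch, panel, path) {
  df <- data.frame(
    panelIndex = arch@qtlIndex,
    chrom = panel@chrom[arch@qtlIndex],
    posCM = panel@posCM[arch@qtlIndex],
    arch@alpha
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
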