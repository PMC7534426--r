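test_that("QTL effects realize the trait 3/4 correlation at 700 QTL", {
  f <- midFounders()
  set.seed(10)
  arch <- sampleQtlEffects(f$panel)
  expect_equal(nrow(arch@alpha), 700L)
  r34 <- cor(arch@alpha[, 3], arch@alpha[, 4])
  expect_gt(r34, 0.63)
  expect_lt(r34, 0.77)
  # all other pairs uncorrelated
  other <- c(cor(arch@alpha[, 1], arch@alpha[, 2]),
             cor(arch@alpha[, 1], arch@alpha[, 3]),
             cor(arch@alpha[, 2], arch@alpha[, 4]))
  expect_true(all(abs(other) < 0.08))
})

test_that("identity effect correlation gives uncorrelated effects", {
  f <- midFounders()
  set.seed(11)
  arch <- sampleQtlEffects(f$panel, effectCorr = diag(4))
  cm <- cor(arch@alpha)
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.08))
})

test_that("non-PSD effect correlation is rejected", {
  f <- smallFounders()
  bad <- diag(4)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(sampleQtlEffects(f$panel, effectCorr = bad), "definite")
})

test_that("realized TBV correlation between traits 3 and 4 is 0.7", {
  f <- midFounders()
  set.seed(12)
  arch <- sampleQtlEffects(f$panel)
  tbv <- computeTbv(f$founders, arch)
  expect_equal(cor(tbv[, 3], tbv[, 4]), 0.7, tolerance = 0.1)
})

test_that("TBV equals the per-locus summation oracle", {
  # 10 individuals, 5 QTL + 3 SNPs, explicit haplotypes
  set.seed(13)
  hap <- matrix(rbinom(8 * 20, 1, 0.5), nrow = 8)
  panel <- toyPanel(8, role = c("QTL", "SNP", "QTL", "QTL", "SNP", "QTL",
                                "SNP", "QTL"))
  cohort <- toyCohort(hap)
  cohort@map <- panel
  alpha <- matrix(rnorm(5 * 4), 5, 4)
  arch <- new("TraitArchitecture", alpha = alpha, effectCorr = diag(4),
              sigmaE2 = rep(NA_real_, 4), targetPlotH2 = rep(0.5, 4),
              qtlIndex = qtlIndices(panel))
  tbv <- computeTbv(cohort, arch)
  G <- dosage(cohort)
  for (i in 1:10) for (t in 1:4) {
    acc <- 0
    for (q in seq_along(arch@qtlIndex))
      acc <- acc + G[i, arch@qtlIndex[q]] * alpha[q, t]
    expect_equal(unname(tbv[i, t]), unname(acc))
  }
})

test_that("reference homozygote has TBV zero; dosage scales effects", {
  panel <- toyPanel(2, role = c("QTL", "SNP"))
  arch <- new("TraitArchitecture",
              alpha = matrix(0.5, 1, 1), effectCorr = matrix(1, 1, 1),
              sigmaE2 = NA_real_, targetPlotH2 = 0.5, qtlIndex = 1L)
  zero <- toyCohort(matrix(0, 2, 2)); zero@map <- panel
  expect_equal(unname(computeTbv(zero, arch)[1, 1]), 0)
  two <- toyCohort(matrix(c(1, 0, 1, 0), 2, 2)); two@map <- panel
  expect_equal(unname(computeTbv(two, arch)[1, 1]), 1.0)
})

test_that("calibration solves the plot-h2 identity exactly", {
  arch <- new("TraitArchitecture",
              alpha = matrix(rnorm(4), 1, 4), effectCorr = diag(4),
              sigmaE2 = rep(NA_real_, 4),
              targetPlotH2 = c(0.5, 1, 0.25, 0.2), qtlIndex = 1L)
  set.seed(14)
  ptbv <- matrix(rnorm(400 * 4), 400, 4)
  v <- apply(ptbv, 2, var)
  out <- calibrateToPlotH2(ptbv, arch)
  expect_equal(out@sigmaE2[1], v[1] * (1 - 0.5) / 0.5)
  expect_equal(out@sigmaE2[2], 0, tolerance = 1e-12)  # h2 = 1
  expect_equal(out@sigmaE2[3], v[3] * 3)
  expect_error(calibrateToPlotH2(matrix(1, 5, 4), arch), "zero variance")
})

test_that("calibrated heritabilities recover on an independent sample", {
  f <- smallFounders()
  set.seed(15)
  arch <- sampleQtlEffects(f$panel)
  arch <- calibrateArchitecture(f$varieties, arch, nPlots = 400L,
                                familySize = 10L)
  # fresh plots, squared correlation of plot TBV and phenotype
  ptbv <- ryegrassGS:::simulateF2PlotTbvs(f$varieties, arch, 800L, 10L)
  pheno <- plotPhenotype(ptbv, arch)
  h2 <- vapply(1:4, function(t) cor(ptbv[, t], pheno[, t])^2, numeric(1))
  expect_lt(max(abs(h2 - arch@targetPlotH2)), 0.055)
})

test_that("plot phenotypes add independent calibrated noise", {
  arch <- new("TraitArchitecture",
              alpha = matrix(rnorm(4), 1, 4), effectCorr = diag(4),
              sigmaE2 = c(0, 1, 1, 4), targetPlotH2 = rep(0.5, 4),
              qtlIndex = 1L)
  set.seed(16)
  ptbv <- matrix(0, 10000, 4)
  y <- plotPhenotype(ptbv, arch)
  expect_equal(y[, 1], ptbv[, 1])             # sigmaE2 = 0: exact
  expect_gt(var(y[, 2]), 0.95)
  expect_lt(var(y[, 2]), 1.05)
  expect_lt(abs(cor(y[, 2], y[, 3])), 0.03)   # independent deviates
  expect_equal(var(y[, 4]), 4, tolerance = 0.2)
})

test_that("single-plant phenotypes use the requested trait's variance", {
  arch <- new("TraitArchitecture",
              alpha = matrix(rnorm(4), 1, 4), effectCorr = diag(4),
              sigmaE2 = c(1, 0, 1, 1), targetPlotH2 = rep(0.5, 4),
              qtlIndex = 1L)
  tbv <- matrix(rnorm(200 * 4), 200, 4)
  expect_equal(singlePlantPhenotype(tbv, arch, trait = 2L), tbv[, 2])
  set.seed(17)
  y <- singlePlantPhenotype(rep(0, 10000), arch, trait = 3L)
  expect_equal(var(y), 1, tolerance = 0.05)
})

test_that("plot TBV is conserved under averaging and effect scaling", {
  f <- smallFounders()
  arch <- smallArch()
  members <- f$varieties[[1]][1:10]
  tbv <- computeTbv(members, arch)
  expect_equal(plotTbv(tbv), colMeans(tbv))
  # scaling one trait's effects scales its TBV variance quadratically
  arch2 <- arch
  arch2@alpha[, 2] <- 3 * arch2@alpha[, 2]
  tbv2 <- computeTbv(f$varieties[[1]], arch2)
  tbv1 <- computeTbv(f$varieties[[1]], arch)
  expect_equal(var(tbv2[, 2]), 9 * var(tbv1[, 2]))
  expect_equal(cor(tbv2[, 3], tbv2[, 4]), cor(tbv1[, 3], tbv1[, 4]))
})
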