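test_that("plot dosage is twice the sampled allele frequency", {
  # 20 plants, counted-allele frequency 0.7 at the first SNP:
  # 28 of 40 haplotypes carry the allele
  alleles <- c(rep(1L, 28), rep(0L, 12))
  hap <- rbind(alleles, matrix(0L, 3, 40), matrix(1L, 1, 40))
  panel <- toyPanel(5)
  cohort <- toyCohort(hap)
  cohort@map <- panel
  d <- plotDosage(cohort, panel, nSample = 20L)
  expect_equal(d[1], 1.4)
  expect_equal(d[2], 0)    # all homozygous reference
  expect_equal(d[5], 2)
  # all heterozygous -> 1.0
  het <- toyCohort(matrix(rep(c(1L, 0L), 20), nrow = 1))
  het@map <- toyPanel(1)
  expect_equal(plotDosage(het, het@map, 20L), 1)
  expect_error(plotDosage(het, het@map, 25L), "cannot sample")
})

test_that("reference population grows append-only with provenance", {
  ref <- newReferencePopulation(10L)
  expect_equal(nrow(ref@X), 0L)
  X <- matrix(runif(5 * 10, 0, 2), 5, 10)
  y <- matrix(rnorm(20), 5, 4)
  ref <- updateReference(ref, X, y, id = paste0("a", 1:5), "F2", 1L, 4L)
  expect_equal(nrow(ref@X), 5L)
  # empty addition unchanged
  ref2 <- updateReference(ref, X[0, ], y[0, ], character(0), "F2", 1L, 5L)
  expect_identical(ref2, ref)
  expect_error(updateReference(ref, X, y, paste0("a", 1:5), "F2", 1L, 5L),
               "duplicate")
  ref <- updateReference(ref, X, y, paste0("b", 1:5), "SYN2", 1L, 10L)
  expect_equal(nrow(referenceAsOf(ref, 4L)@X), 5L)
  expect_equal(nrow(referenceAsOf(ref, 10L)@X), 10L)
})

test_that("Gibbs sampler matches the closed-form ridge solution", {
  set.seed(30)
  n <- 50; p <- 20
  Xraw <- matrix(runif(n * p, 0, 2), n, p)
  X <- sweep(Xraw, 2, colMeans(Xraw))  # the fit centers identically
  b <- rnorm(p, 0, 0.3)
  y <- drop(X %*% b) + rnorm(n)
  varE <- 1; varB <- 0.09
  lambda <- varE / varB
  oracle <- drop(solve(crossprod(X) + diag(lambda, p),
                       crossprod(X, y - mean(y))))

  ref <- newReferencePopulation(p, 1L)
  ref <- updateReference(ref, Xraw, matrix(y), paste0("r", 1:n),
                         "F2", 1L, 4L)
  set.seed(31)
  est <- fitBrr(ref, traits = 1L,
                chain = list(nIter = 20000L, burnIn = 2000L),
                fixVarE = varE, fixVarB = varB)
  expect_gt(cor(est@effects[, 1], oracle), 0.995)
  expect_lt(max(abs(est@effects[, 1] - oracle)), 0.05)
})

test_that("the sampler is reproducible and handles degenerate phenotypes", {
  set.seed(32)
  n <- 30; p <- 15
  X <- matrix(runif(n * p, 0, 2), n, p)
  y <- matrix(rnorm(n * 4), n, 4)
  ref <- updateReference(newReferencePopulation(p), X, y,
                         paste0("r", 1:n), "F2", 1L, 4L)
  ch <- list(nIter = 500L, burnIn = 100L)
  set.seed(33); e1 <- fitBrr(ref, traits = c(1L, 3L), chain = ch)
  set.seed(33); e2 <- fitBrr(ref, traits = c(1L, 3L), chain = ch)
  expect_identical(e1@effects, e2@effects)

  refConst <- updateReference(newReferencePopulation(p), X,
                              matrix(5, n, 4), paste0("c", 1:n),
                              "F2", 1L, 4L)
  expect_warning(ez <- fitBrr(refConst, traits = 1L, chain = ch),
                 "zero-variance")
  expect_true(all(ez@effects == 0))
})

test_that("a single strong marker recovers the OLS slope", {
  set.seed(34)
  n <- 500
  x <- rbinom(n, 2, 0.5)
  y <- 2 * x + rnorm(n, 0, 0.5)
  ref <- updateReference(newReferencePopulation(1L, 1L),
                         matrix(as.numeric(x)), matrix(y),
                         paste0("r", 1:n), "F2", 1L, 4L)
  est <- fitBrr(ref, traits = 1L, chain = list(nIter = 3000L,
                                               burnIn = 500L))
  ols <- coef(lm(y ~ x))[2]
  expect_equal(unname(est@effects[1, 1]), unname(ols), tolerance = 0.1)
})

test_that("GEBVs are centered dot products with the estimated effects", {
  set.seed(35)
  p <- 100
  eff <- matrix(rnorm(p * 2), p, 2)
  centers <- runif(p, 0, 2)
  est <- new("MarkerEffectEstimate", mu = c(0, 0), effects = eff,
             varE = c(1, 1), varB = c(0.1, 0.1), centers = centers,
             chain = list(nIter = 1L, burnIn = 0L))
  x <- matrix(runif(3 * p, 0, 2), 3, p)
  got <- computeGebv(x, est)
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) for (t in 1:2)
    oracle[i, t] <- sum((x[i, ] - centers) * eff[, t])
  expect_equal(unname(got), oracle)
  # zero effects -> zero GEBV; single-SNP arithmetic
  est0 <- est; est0@effects[] <- 0
  expect_true(all(computeGebv(x, est0) == 0))
  expect_error(computeGebv(x[, 1:10], est), "SNPs")
})

test_that("accuracy improves with reference size", {
  set.seed(36)
  p <- 300; nBig <- 200
  b <- rnorm(p, 0, 1 / sqrt(p))
  X <- matrix(runif((nBig + 100) * p, 0, 2), nBig + 100, p)
  g <- drop(X %*% b)
  y <- g + rnorm(nBig + 100, 0, sd(g))
  mkRef <- function(n) {
    updateReference(newReferencePopulation(p, 1L),
                    X[seq_len(n), , drop = FALSE],
                    matrix(y[seq_len(n)]), paste0("r", seq_len(n)),
                    "F2", 1L, 4L)
  }
  ch <- list(nIter = 1500L, burnIn = 300L)
  val <- nBig + 1:100
  accOf <- function(n) {
    est <- fitBrr(mkRef(n), traits = 1L, chain = ch)
    cor(drop(computeGebv(X[val, ], est)), g[val])
  }
  set.seed(37)
  accSmall <- accOf(50L)
  accLarge <- accOf(200L)
  expect_gt(accLarge, accSmall)
})
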