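test_that("a fully homozygous parent transmits one of its haplotypes", {
  hap <- cbind(rep(0L, 50), rep(0L, 50))
  cohort <- toyCohort(hap)
  g <- meiosis(cohort, 1L)
  expect_equal(g, rep(0L, 50))
  hap2 <- cbind(rep(1L, 50), rep(1L, 50))
  expect_equal(meiosis(toyCohort(hap2), 1L), rep(1L, 50))
})

test_that("crossover counts average one per chromosome per meiosis", {
  # chromatids all-0 / all-1 on a dense full-span grid: allele switches
  # along the gamete reveal the crossover points
  cohort <- denseHetParent()
  set.seed(20)
  switches <- vapply(seq_len(10000), function(i) {
    g <- meiosis(cohort, 1L)
    sum(diff(g) != 0L)
  }, numeric(1))
  expect_gt(mean(switches), 0.97)
  expect_lt(mean(switches), 1.03)
})

test_that("a heterozygous locus is transmitted fairly", {
  hap <- cbind(rep(0L, 10), rep(1L, 10))
  cohort <- toyCohort(hap)
  set.seed(21)
  tx <- vapply(seq_len(10000), function(i) meiosis(cohort, 1L)[5],
               integer(1))
  expect_equal(mean(tx), 0.5, tolerance = 0.015)
})

test_that("cross obeys Mendelian expectations and rejects selfing", {
  # AA x aa -> all Aa
  hap <- cbind(c(1L), c(1L), c(0L), c(0L))
  parents <- toyCohort(matrix(hap, nrow = 1))
  off <- cross(parents, 1L, 2L, nOffspring = 50L)
  expect_true(all(dosage(off) == 1L))
  expect_error(cross(parents, 1L, 1L, 10L), "self")

  # Aa x Aa -> 1/4, 1/2, 1/4
  hapHet <- matrix(c(1L, 0L, 1L, 0L), nrow = 1)
  het <- toyCohort(hapHet)
  set.seed(22)
  off2 <- cross(het, 1L, 2L, nOffspring = 10000L)
  tab <- tabulate(dosage(off2)[, 1] + 1L, 3) / 10000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(tab - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("F1 families draw parents evenly across distinct varieties", {
  f <- smallFounders()
  set.seed(23)
  fam <- makeF1Families(f$varieties, nFamilies = 120L, familySize = 4L)
  expect_equal(nInd(fam), 480L)
  ln <- lineage(fam)
  expect_equal(length(unique(ln$family)), 120L)
  # the two parents of each family come from different varieties
  motherVar <- sub("_.*", "", ln$mother)
  fatherVar <- sub("_.*", "", ln$father)
  expect_true(all(motherVar != fatherVar))
  # multinomial draw oracle: 240 parent draws over 6 varieties
  counts <- table(c(motherVar[!duplicated(ln$family)],
                    fatherVar[!duplicated(ln$family)]))
  expected <- 240 / 6
  se <- sqrt(240 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - expected) < 3.5 * se))
  expect_error(makeF1Families(f$varieties[1], 5L, 4L), "2 source")
})

test_that("family intermating excludes selfing and conserves frequency", {
  f <- smallFounders()
  fam <- f$varieties[[1]][1:2]
  off <- intermateFamily(fam, 30L)
  expect_true(all(lineage(off)$mother != lineage(off)$father))
  expect_true(all(lineage(off)$mother %in% fam@id))
  expect_error(intermateFamily(f$varieties[[1]][1], 5L), "fewer than 2")

  set.seed(24)
  fam8 <- f$varieties[[2]][1:8]
  big <- intermateFamily(fam8, 10000L)
  pf <- alleleFreq(fam8)
  of <- alleleFreq(big)
  se <- sqrt(pmax(pf * (1 - pf), 1e-9) / (2 * 10000))
  # gene-counting conservation within 3 SEs at most loci; transmission
  # noise from only 8 parents adds a small floor
  expect_lt(mean(abs(of - pf)), 3 * mean(se) + 0.05)
  expect_lt(max(abs(of - pf)), 0.15)
})

test_that("polycross uses all 8 parents evenly and never selfs", {
  f <- smallFounders()
  parents <- f$varieties[[3]][1:8]
  set.seed(25)
  syn <- polycross(parents, nOffspring = 4000L)
  ln <- lineage(syn)
  expect_true(all(ln$mother != ln$father))
  contrib <- table(c(ln$mother, ln$father))
  expect_length(contrib, 8L)
  se <- sqrt(8000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(contrib - 1000) < 3 * se))
  expect_error(polycross(f$varieties[[3]][1:5]), "exactly 8")
  dup <- parents
  dup@id[2] <- dup@id[1]
  expect_error(polycross(dup), "duplicate")

  # identical homozygous parents give identical homozygous offspring
  hom <- toyCohort(matrix(rep(c(1L, 1L), 8), nrow = 1))
  synHom <- polycross(hom, 50L)
  expect_true(all(dosage(synHom) == 2L))
})

test_that("selection indices weight standardized traits", {
  expect_equal(selectionIndex(matrix(3, 1, 3), standardize = FALSE), 3)
  expect_equal(selectionIndex(matrix(c(1, 0, -1), 1, 3),
                              standardize = FALSE), 0)
  set.seed(26)
  v <- matrix(rnorm(100 * 3), 100, 3)
  got <- phenotypicIndex(v)
  z <- scale(v)
  oracle <- drop(z %*% rep(1 / 3, 3))
  expect_equal(order(got), order(oracle))
  expect_equal(gebvIndex(v), got)
  expect_error(selectionIndex(v, weights = c(1, 1, 1)), "sum to 1")
})

test_that("truncation selection is deterministic under ties", {
  expect_equal(sort(selectTop(1:100, 50L)), 51:100)
  expect_equal(selectTop(rep(1, 10), 3L), 1:3)
  set.seed(27)
  sc <- rnorm(50)
  expect_equal(sort(selectTop(sc, 10L)), sort(order(-sc)[1:10]))
  expect_error(selectTop(1:3, 5L), "more candidates")
})

test_that("heading-date grouping partitions by sorted blocks", {
  set.seed(28)
  hd <- rnorm(40)
  g <- groupByHeading(hd, groupSize = 8L)
  expect_length(g$groups, 5L)
  ranges <- t(vapply(g$groups, function(i) range(hd[i]), numeric(2)))
  # consecutive blocks: each group's range below the next group's
  expect_true(all(ranges[-1, 1] >= ranges[-5, 2]))
  expect_equal(g$category, c("early", "early", "intermediate", "late",
                             "late"))
  expect_error(groupByHeading(rnorm(10), 8L), "divisible")
  # equal phenotypes: deterministic by id
  g1 <- groupByHeading(rep(0, 16), 8L, ids = letters[1:16])
  g2 <- groupByHeading(rep(0, 16), 8L, ids = letters[1:16])
  expect_identical(g1, g2)
})
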