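test_that("the cycle calendar reproduces the stated availabilities", {
  cal <- eventCalendar(1L)
  expect_equal(unname(cal["syn2Selection"]), 11L)
  expect_equal(unname(cal["f2SpAvailable"]), 6L)
  expect_equal(unname(cal["syn2Available"]), 12L)
  expect_equal(unname(cal["syn3"] - cal["f1Cross"]), 11L)
  # offset arithmetic for cycles 1, 2 and 8
  for (c in c(1L, 2L, 8L)) {
    cal <- eventCalendar(c)
    expect_equal(unname(cal["f2Phenotype"]), c + 3L)
    expect_equal(unname(cal["f2Selection"]), c + 4L)
    expect_equal(unname(cal["syn2Phenotype"]), c + 9L)
    expect_equal(unname(cal["syn2Selection"]), c + 10L)
  }
  # cycle-8 F2 phenotypes and cycle-2 SYN2 phenotypes are both in the
  # reference by year 11, when cycle-1 SYN2 groups are selected
  expect_lte(unname(eventCalendar(8L)["f2Phenotype"]), 11L)
  expect_lte(unname(eventCalendar(2L)["syn2Phenotype"]), 11L)
  expect_error(eventCalendar(0L), ">= 1")
})

test_that("36 years correspond to 25 overlapping cycles", {
  cfg <- scenarioConfig("Phen-Y12")
  expect_equal(cfg$years, 36L)
  expect_equal(cfg$nCycles, 25L)
  expect_equal(cfg$independentCycles, 11L)
  # the last cycle completes exactly at the horizon
  expect_equal(unname(eventCalendar(cfg$nCycles)["syn3"]), 36L)
  expect_equal(scenarioConfig("GS")$independentCycles, 5L)
  expect_error(scenarioConfig("GS-XX"), "unknown scenario")
  expect_error(scenarioConfig("GS", nSPSelected = 33L), "multiple")
})

test_that("independent cycles show no cumulative gain and stable variance", {
  f <- smallFounders()
  arch <- smallArch()
  set.seed(50)
  cfg <- scenarioConfig("Phen-Y12", years = 14L, nCycles = 10L,
                        nF1Families = 100L, familySize = 6L, nSelF2 = 20L,
                        spFamilySize = 8L, nSPSelected = 80L,
                        groupSize = 4L, synSize = 8L, nSynSelected = 8L,
                        plotSampleSize = 4L)
  res <- runScenario(cfg, f$panel, f$varieties, arch)
  dg <- res$gain$deltaG
  # all cycles start from the unselected initial varieties: no trend
  expect_lt(abs(mean(dg)), 0.15)
  av <- res$additiveVariance$standardized
  expect_gt(mean(av), 0.75)
  expect_lt(mean(av), 1.25)
  # a phenotypic scenario never builds a reference population
  expect_equal(nrow(res$referenceSize), 0L)
})

test_that("scenario runs are reproducible under a fixed seed", {
  f <- smallFounders()
  arch <- smallArch()
  cfg <- smallScenario("Phen", years = 16L, nCycles = 5L)
  set.seed(51); r1 <- runScenario(cfg, f$panel, f$varieties, arch)
  set.seed(51); r2 <- runScenario(cfg, f$panel, f$varieties, arch)
  expect_identical(r1$gain, r2$gain)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("the GS reference grows by one F2 batch per year plus SYN2", {
  f <- smallFounders()
  arch <- smallArch()
  cfg <- smallScenario("GS", years = 15L, nCycles = 6L)
  set.seed(52)
  res <- runScenario(cfg, f$panel, f$varieties, arch)
  rs <- res$referenceSize
  # calendar replay oracle: F2 of cycle c lands in year c + 3, SYN2 of
  # cycle c in year c + 9
  expected <- vapply(rs$year, function(y) {
    cfg$nF1Families * max(0L, min(y - 3L, cfg$nCycles)) +
      cfg$nSyn * max(0L, min(y - 9L, cfg$nCycles))
  }, numeric(1))
  expect_equal(rs$nRecords, expected)
  # +250-per-year analogue while F2 additions are running
  growth <- diff(rs$nRecords[rs$year >= 4 & rs$year <= cfg$nCycles + 3])
  expect_true(all(growth >= cfg$nF1Families))
})

test_that("GS scenarios outgain phenotypic scenarios at matched structure", {
  f <- smallFounders()
  arch <- smallArch()
  set.seed(53)
  resP <- runScenario(smallScenario("Phen", years = 20L, nCycles = 9L),
                      f$panel, f$varieties, arch)
  set.seed(53)
  resG <- runScenario(smallScenario("GS", years = 20L, nCycles = 9L),
                      f$panel, f$varieties, arch)
  idxTraits <- c("trait1", "trait3", "trait4")
  lastGain <- function(res) {
    g <- res$gain
    mean(g$deltaG[g$cycle == max(g$cycle) & g$trait %in% idxTraits])
  }
  expect_gt(lastGain(resG), lastGain(resP))
  # genomic runs record GEBV accuracies at both plot stages
  expect_true(all(c("F2_plot", "F2_SP", "SYN2_plot") %in%
                    resG$accuracy$stage))
  expect_false("SYN2_SP" %in% resG$accuracy$stage)
})

test_that("GS-SP recruits SYN2 single plants and records their accuracy", {
  f <- smallFounders()
  arch <- smallArch()
  set.seed(54)
  res <- runScenario(smallScenario("GS-SP", years = 21L, nCycles = 10L),
                     f$panel, f$varieties, arch)
  expect_true("SYN2_SP" %in% res$accuracy$stage)
  # accuracies are well-defined correlations
  expect_true(all(is.finite(res$accuracy$r)))
  expect_true(all(abs(res$accuracy$r) <= 1))
})

test_that("Y12 schemes recruit from SYN2 output once it exists", {
  f <- smallFounders()
  arch <- smallArch()
  set.seed(56)
  res <- runScenario(smallScenario("GS-Y12", years = 26L, nCycles = 14L,
                                   independentCycles = 11L),
                     f$panel, f$varieties, arch)
  g <- res$gain
  expect_equal(max(g$cycle), 14L)
  idx <- c("trait1", "trait3", "trait4")
  early <- mean(g$deltaG[g$cycle <= 11 & g$trait %in% idx])
  late <- mean(g$deltaG[g$cycle >= 12 & g$trait %in% idx])
  # cycles 12-14 descend from the selected SYN2 plants of cycles 1-3
  expect_gt(late, early)
})

test_that("stage counts follow the configuration", {
  f <- smallFounders()
  arch <- smallArch()
  cfg <- smallScenario("GS", years = 12L, nCycles = 1L)
  set.seed(55)
  res <- runScenario(cfg, f$panel, f$varieties, arch)
  acc <- res$accuracy
  # one cycle: F2 plot selection in year 5, SYN2 selection in year 11
  expect_equal(unique(acc$year[acc$stage == "F2_plot"]), 5L)
  expect_equal(unique(acc$year[acc$stage == "SYN2_plot"]), 11L)
  expect_equal(nrow(res$gain), 4L)  # one cycle x four traits
})
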