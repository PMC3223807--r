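test_that("region pairs are bit-reproducible and correctly labelled", {
  scn <- syntheticScenario(nDistractors = 3)
  p1 <- generateRegionPair(scn, seed = 42)
  p2 <- generateRegionPair(scn, seed = 42)
  expect_identical(biomassValues(p1$regionA), biomassValues(p2$regionA))
  expect_identical(biomassValues(p1$regionB), biomassValues(p2$regionB))
  expect_identical(p1$truth$mapping, p2$truth$mapping)
  expect_false(identical(biomassValues(p1$regionB),
                         biomassValues(generateRegionPair(scn, 43)$regionB)))

  # the published region-B columns really carry the mapped roles: the
  # target is pinned low after region B's collapse, its mirror rises
  tr <- p1$truth
  post <- tr$years >= 1992
  stT <- tr$statesB[, tr$mapping[[tr$target]]]
  expect_lt(mean(stT[post]), 1.5)
  expect_gt(mean(stT[!post]), 2.2)
  st4 <- tr$statesB[, tr$mapping[[tr$coreA[4]]]]
  expect_gt(mean(st4[post]), mean(st4[!post]))
  expect_equal(tr$hiddenB, ifelse(tr$years >= 1992, 2L, 1L))
})

test_that("a no-collapse region has a constant true trajectory", {
  scn <- syntheticScenario(nDistractors = 2, collapseYearB = NA)
  pair <- generateRegionPair(scn, seed = 3)
  expect_true(all(pair$truth$hiddenB == 1L))
  expect_equal(unique(pair$truth$hiddenA), c(1L, 2L))
})

test_that("empirical conditional frequencies match the generating CPTs", {
  scn <- syntheticScenario(nYears = 10000L, startYear = 1L,
                           collapseYearA = 5001L, collapseYearB = 5001L,
                           nDistractors = 0L)
  pair <- generateRegionPair(scn, seed = 7)
  tr <- pair$truth
  st <- tr$statesA
  reg <- tr$hiddenA
  # core 4 reads the target within the same year
  for (r in 1:2) for (x in 1:3) {
    rows <- which(reg == r & st[, 1] == x)
    if (length(rows) < 300) next
    emp <- tabulate(st[rows, 4], 3) / length(rows)
    expect_lt(max(abs(emp - funcEquiv:::.coreDistribution(
      scn, 4L, r, prevSelf = NULL, parentStates = x))), 0.02)
  }
  # the target's post-collapse pin
  rows <- which(reg == 2L)
  emp <- tabulate(st[rows, 1], 3) / length(rows)
  expect_lt(max(abs(emp - funcEquiv:::.coreDistribution(scn, 1L, 2L))), 0.02)
})

test_that("regime-shift series: degenerate and counting contracts", {
  flat <- matrix(1 / 2, 2, 2)
  sim <- generateRegimeShiftSeries(10, collapseYear = 3000,
                                   preCPT = list(a = flat),
                                   postCPT = list(a = flat),
                                   startYear = 1990L, seed = 1)
  expect_true(all(sim$states == 1L))

  sim2 <- generateRegimeShiftSeries(45, 1988, list(a = flat), list(a = flat),
                                    startYear = 1963L, seed = 2)
  expect_equal(sum(sim2$states == 1L), 25L)
  expect_equal(sum(sim2$states == 2L), 20L)
})

test_that("identical pre/post CPTs give a stationary series", {
  # mild persistence keeps the chi-square comparison close to nominal
  cpt <- matrix(c(0.45, 0.30, 0.25,
                  0.30, 0.40, 0.30,
                  0.25, 0.30, 0.45), 3, byrow = TRUE)
  ok <- vapply(1:100, function(s) {
    sim <- generateRegimeShiftSeries(44, 1985, list(a = cpt), list(a = cpt),
                                     startYear = 1963L, seed = 3000 + s)
    x <- stateRecords(sim$dataset)[, 1]
    tab <- rbind(tabulate(x[1:22], 3), tabulate(x[23:44], 3))
    suppressWarnings(stats::chisq.test(tab)$p.value) > 0.01
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("recovery metrics behave at their extremes", {
  pair <- generateRegionPair(syntheticScenario(nDistractors = 3), seed = 9)
  tr <- pair$truth
  perfect <- new("EquivalenceResult", assignment = tr$mapping,
                 finalScore = 0, bestAssignment = tr$mapping, bestScore = 0,
                 trace = 0, accepted = 0L, schedule = list())
  expect_equal(evaluateRecovery(perfect, tr)$mappingRecovery, 1)

  # random assignment over a pool of 20 for 5 slots: expected 1/20 per slot
  pool <- sprintf("spB%02d", 1:20)
  hits <- vapply(1:10000, function(s) {
    a <- funcEquiv:::withSeed(s, setNames(sample(pool, 5), tr$coreA))
    mean(a == tr$mapping)
  }, 0)
  expect_equal(mean(hits), 0.05, tolerance = 0.01 / 0.05)

  # label alignment makes the hidden accuracy inversion-invariant
  ps <- data.frame(year = tr$years, observed = 1L, predicted = 1L,
                   mapState = ifelse(tr$years >= 1992, 2L, 1L))
  accA <- evaluateRecovery(ps, tr)$hiddenAccuracy
  ps$mapState <- 3L - ps$mapState
  expect_equal(evaluateRecovery(ps, tr)$hiddenAccuracy, accA)
  expect_equal(accA, 1)

  # edge precision/recall against the true within-year structure
  dag <- DAGStructure(tr$coreA, list(spA01 = "spA02"))
  er <- evaluateRecovery(dag, tr)
  expect_equal(er$edgePrecision, 1)
  expect_equal(er$edgeRecall, 1 / nrow(tr$trueEdges))
})

test_that("regime-shift detection reads the terminal collapsed run", {
  yrs <- 1980:1999
  mapState <- c(rep(1L, 10), rep(2L, 10))
  d <- detectRegimeShift(mapState, yrs, collapseYear = 1990)
  expect_equal(d$switchYear, 1990L)
  expect_equal(d$postStability, 1)
  expect_true(is.na(detectRegimeShift(rep(1L, 20), yrs, 1990)$switchYear))
})

test_that("the full pipeline recovers mapping and regime on average", {
  recs <- numeric(0)
  hids <- numeric(0)
  for (s in 1:20) {
    pair <- generateRegionPair(syntheticScenario(), seed = s)
    tr <- pair$truth
    res <- runTransferPipeline(pair$regionA, pair$regionB, 1988, tr$target,
                               collapseYearB = 1992,
                               schedule = annealingSchedule(seed = s),
                               seed = s)
    recs <- c(recs, evaluateRecovery(res$equivalence, tr)$mappingRecovery)
    hids <- c(hids, evaluateRecovery(res$transfer, tr)$hiddenAccuracy)
  }
  expect_gte(mean(recs), 0.8)
  expect_gte(mean(hids), 0.9)
})
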