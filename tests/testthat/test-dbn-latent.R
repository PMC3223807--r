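test_that("transition pairing keeps consecutive years only", {
  d <- randomDataset(46, c(a = 2L), seed = 1)
  td <- makeTransitionDataset(d, 1963:2008)
  expect_equal(nRecords(td), 45L)
  expect_true(all(!td@newSegment[-1]))

  d2 <- randomDataset(4, c(a = 2L), seed = 2)
  td2 <- makeTransitionDataset(d2, c(2000L, 2001L, 2003L, 2004L))
  expect_equal(nRecords(td2), 2L)
  expect_equal(td2@newSegment, c(TRUE, TRUE))

  expect_error(makeTransitionDataset(randomDataset(1, c(a = 2L), seed = 3),
                                     2000L), "consecutive")
  expect_error(makeTransitionDataset(d2, c(2000L, 2002L, 2004L, 2006L)),
               "consecutive")
})

test_that("REVEAL recovers self-edges of independent AR(1) species", {
  sticky <- matrix(c(0.85, 0.1, 0.05,
                     0.1, 0.8, 0.1,
                     0.05, 0.1, 0.85), 3, byrow = TRUE)
  ok <- vapply(1:10, function(s) {
    sim <- generateRegimeShiftSeries(200, collapseYear = 3000,
                                     preCPT = list(a = sticky, b = sticky,
                                                   c = sticky),
                                     postCPT = list(a = sticky, b = sticky,
                                                    c = sticky),
                                     startYear = 1900L, seed = 40 + s)
    td <- makeTransitionDataset(sim$dataset, sim$years)
    found <- revealSearch(td, maxParents = 2)
    all(vapply(names(found), function(v) identical(found[[v]], v), TRUE))
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  d <- randomDataset(30, c(a = 2L, b = 2L), seed = 5)
  td <- makeTransitionDataset(d, 1971:2000)
  expect_equal(unname(lengths(revealSearch(td, maxParents = 0))), c(0L, 0L))
})

test_that("greedy REVEAL never beats the exhaustive parent-set optimum", {
  d <- randomDataset(60, c(a = 2L, b = 2L, c = 2L), seed = 6)
  td <- makeTransitionDataset(d, 1941:2000)
  found <- revealSearch(td, targets = "c", maxParents = 3)[["c"]]
  score <- function(pa) {
    stacked <- cbind(td@prev, td@cur[, "c", drop = FALSE])
    idx <- if (length(pa)) match(pa, c("a", "b", "c")) else integer(0)
    funcEquiv:::.familyScoreC(stacked, 4L, idx, rep(2L, 4), "bic")
  }
  subsets <- list(character(0), "a", "b", "c", c("a", "b"), c("a", "c"),
                  c("b", "c"), c("a", "b", "c"))
  best <- max(vapply(subsets, score, 0))
  expect_lte(score(found), best + 1e-9)
})

test_that("forward-backward matches brute-force path enumeration", {
  for (s in 1:6) {
    fx <- funcEquiv:::withSeed(50 + s, {
      P <- sample(3:8, 1)
      A <- matrix(runif(4, 0.1, 1), 2)
      A <- A / rowSums(A)
      init <- runif(2, 0.1, 1)
      init <- init / sum(init)
      E <- matrix(runif(P * 2, 0.05, 1), P, 2)
      list(P = P, A = A, init = init, E = E)
    })
    fb <- funcEquiv:::.forwardBackward(fx$init, fx$A, fx$E,
                                       c(TRUE, rep(FALSE, fx$P - 1)))
    oracle <- pathEnumeration(fx$init, fx$A, fx$E)
    expect_equal(fb$ll, oracle$ll, tolerance = 1e-9)
    expect_equal(fb$smoothed, oracle$smoothed, tolerance = 1e-9)
    expect_equal(fb$filtered, oracle$filtered, tolerance = 1e-9)
  }
})

test_that("EM recovers a sticky transition matrix from clean emissions", {
  A <- matrix(c(0.9, 0.1, 0.15, 0.85), 2, byrow = TRUE)
  emit <- rbind(c(1, 0, 0), c(0, 0, 1))  # deterministic per hidden state
  sim <- simHMMSeries(200, A, emit, seed = 7)
  d <- DiscreteDataset(cbind(y = sim$y), arities = c(y = 3L))
  td <- makeTransitionDataset(d, seq_len(200) + 1800L)
  sk <- dbnSkeleton(list(y = character(0)), "y", c(y = 3L))
  fit <- fitEM(sk, td, nRestarts = 6, seed = 3)
  m <- fit$model
  # align labels by the emission mode before comparing
  flip <- which.max(m@hiddenCPTs[["y"]][1, , 1]) != 1
  Ahat <- if (flip) m@transition[2:1, 2:1] else m@transition
  expect_lt(max(abs(Ahat - A)), 0.05)
})

test_that("EM log-likelihood never decreases within a restart", {
  for (s in 1:12) {
    sim <- generateRegimeShiftSeries(
      40, 1920,
      preCPT = list(a = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
                    b = matrix(0.5, 2, 2)),
      postCPT = list(a = matrix(c(0.2, 0.8, 0.7, 0.3), 2, byrow = TRUE),
                     b = matrix(0.5, 2, 2)),
      startYear = 1900L, seed = 70 + s)
    td <- makeTransitionDataset(sim$dataset, sim$years)
    sk <- dbnSkeleton(list(a = "b", b = "b"), "a", c(a = 2L, b = 2L))
    fit <- fitEM(sk, td, nRestarts = 4, seed = s)
    for (tr in fit$report$traces) {
      if (length(tr) > 1) expect_true(all(diff(tr) >= -1e-9))
    }
    expect_equal(fit$report$logLik,
                 max(vapply(fit$report$traces, max, 0)), tolerance = 1e-9)
  }
})

test_that("deterministic self-lag dynamics predict perfectly", {
  # target is a deterministic function of its own previous state (a state
  # cycle); predictions must equal the observations, whatever H does
  y <- rep(c(1L, 2L, 3L), length.out = 30)
  d <- DiscreteDataset(cbind(y = y), arities = c(y = 3L))
  sk <- dbnSkeleton(list(y = "y"), "y", c(y = 3L))
  tc <- array(0, c(3, 2, 3))
  for (j in 1:3) for (h in 1:2) tc[j, h, j %% 3L + 1L] <- 1
  sk@hiddenCPTs[["y"]] <- tc
  ps <- predictOneStep(sk, d, seq_len(30) + 1950L)
  expect_equal(ps$predicted, ps$observed)
  expect_true(ps$fromPrior[1] && !any(ps$fromPrior[-1]))
})

test_that("an irrelevant hidden state changes nothing", {
  funcEquiv:::withSeed(9, {
    y <- sample.int(3L, 40, replace = TRUE)
    x <- sample.int(2L, 40, replace = TRUE)
    d <- DiscreteDataset(cbind(y = y, x = x), arities = c(y = 3L, x = 2L))
    sk <- dbnSkeleton(list(y = "x", x = character(0)), "y",
                      c(y = 3L, x = 2L), hiddenChildren = "y")
    emis <- matrix(runif(6, 0.1, 1), 2, 3)
    emis <- emis / rowSums(emis)
    tc <- array(0, c(2, 2, 3))
    for (h in 1:2) tc[, h, ] <- emis  # identical across hidden states
    sk@hiddenCPTs[["y"]] <- tc
    sk@transition <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
    ps <- predictOneStep(sk, d, seq_len(40) + 1950L)
    # the H-free prediction conditions on the lagged parent only
    manual <- vapply(seq_len(nrow(ps)), function(i)
      which.max(emis[x[i], ]), 0L)
    expect_equal(ps$predicted, manual)
  })
})

test_that("one-step predictions are causal", {
  fx <- simHMMSeries(30, matrix(c(0.9, 0.1, 0.1, 0.9), 2),
                     rbind(c(0.8, 0.15, 0.05), c(0.05, 0.15, 0.8)),
                     seed = 10)
  d <- DiscreteDataset(cbind(y = fx$y), arities = c(y = 3L))
  sk <- dbnSkeleton(list(y = character(0)), "y", c(y = 3L))
  fit <- fitEM(sk, makeTransitionDataset(d, seq_len(30) + 1950L),
               nRestarts = 3, seed = 2)
  ps <- predictOneStep(fit$model, d, seq_len(30) + 1950L)
  # perturb the future: predictions before the change must not move
  y2 <- fx$y
  y2[20:30] <- rev(y2[20:30])
  d2 <- DiscreteDataset(cbind(y = y2), arities = c(y = 3L))
  ps2 <- predictOneStep(fit$model, d2, seq_len(30) + 1950L)
  expect_equal(ps$predicted[ps$year <= 1969], ps2$predicted[ps2$year <= 1969])
  expect_equal(ps$pPredicted[ps$year <= 1969],
               ps2$pPredicted[ps2$year <= 1969])
})

test_that("smoothing recovers deterministic hidden states exactly", {
  h <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L)
  y <- h  # observation = hidden state
  d <- DiscreteDataset(cbind(y = y), arities = c(y = 2L))
  sk <- dbnSkeleton(list(y = character(0)), "y", c(y = 2L))
  tc <- array(c(1, 0, 0, 1), c(1, 2, 2))
  sk@hiddenCPTs[["y"]] <- tc
  sk@transition <- matrix(c(0.8, 0.2, 0.2, 0.8), 2)
  hs <- inferHiddenStates(sk, d, seq_len(8) + 1950L)
  expect_equal(hs$mapState, h[-1])
  expect_equal(hs$pSmoothed, as.numeric(h[-1] == 2L), tolerance = 1e-12)
})

test_that("time reversal of a time-symmetric chain reverses the posteriors", {
  # symmetric transition + uniform initial: the latent chain is
  # reversible, so reversing the emission sequence reverses the smoothing
  funcEquiv:::withSeed(14, {
    E <- matrix(runif(16, 0.05, 1), 8, 2)
    A <- matrix(c(0.85, 0.15, 0.15, 0.85), 2)
    init <- c(0.5, 0.5)
    seg <- c(TRUE, rep(FALSE, 7))
    a <- funcEquiv:::.forwardBackward(init, A, E, seg)
    b <- funcEquiv:::.forwardBackward(init, A, E[8:1, ], seg)
    expect_equal(a$smoothed, b$smoothed[8:1, ], tolerance = 1e-10)
    expect_equal(a$ll, b$ll, tolerance = 1e-10)
  })
})

test_that("identity transfer is a no-op and models round-trip as JSON", {
  pair <- generateRegionPair(syntheticScenario(nDistractors = 2), seed = 5)
  tr <- pair$truth
  dA <- discretizeBiomass(pair$regionA, method = "equal_width",
                          transform = "log")
  dSel <- subsetVariables(dA, tr$coreA)
  td <- makeTransitionDataset(dSel, tr$years)
  inter <- revealSearch(td, maxParents = 2, excludeSelf = tr$target)
  fit <- fitEM(dbnSkeleton(inter, tr$target, arities(dSel)), td,
               nRestarts = 3, seed = 1)
  idmap <- setNames(tr$coreA, tr$coreA)
  ps0 <- predictOneStep(fit$model, dSel, tr$years)
  ps1 <- transferModel(fit$model, idmap, dSel, tr$years)
  expect_equal(ps1$predicted, ps0$predicted)
  expect_equal(ps1$pSmoothed, ps0$pSmoothed)
  expect_error(transferModel(fit$model, idmap[-1], dSel, tr$years),
               "unmapped slot")

  f <- withr::local_tempfile(fileext = ".json")
  writeDBNModel(fit$model, f)
  m2 <- readDBNModel(f)
  ps2 <- predictOneStep(m2, dSel, tr$years)
  expect_equal(ps2$predicted, ps0$predicted)
  expect_equal(ps2$pSmoothed, ps0$pSmoothed, tolerance = 1e-12)

  fc <- withr::local_tempfile(fileext = ".csv")
  writePredictionSeries(ps0, fc)
  expect_true(all(c("year", "observed", "predicted", "p_hidden_state1",
                    "map_state") %in% names(read.csv(fc))))
})
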