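# a small donor problem whose data2 is data1 with renamed columns plus
# independent distractors; scoring defaults to the refit BIC unless stated
renamedCopyProblem <- function(seed, nDistract = 3, scoreKind = "bic") {
  funcEquiv:::withSeed(seed, {
    a <- sample.int(3L, 40, replace = TRUE)
    noisy <- function(x) ifelse(runif(40) < 0.8, x, sample.int(3L, 40, TRUE))
    rec1 <- cbind(u = a, v = noisy(a), w = noisy(4L - a))
    d1 <- DiscreteDataset(rec1, setNames(rep(3L, 3), colnames(rec1)))
    rec2 <- rec1
    colnames(rec2) <- c("cu", "cv", "cw")
    for (i in seq_len(nDistract)) {
      rec2 <- cbind(rec2, sample.int(3L, 40, replace = TRUE))
      colnames(rec2)[ncol(rec2)] <- paste0("d", i)
    }
    d2 <- DiscreteDataset(rec2, setNames(rep(3L, ncol(rec2)),
                                         colnames(rec2)))
    dag <- DAGStructure(c("u", "v", "w"), list(v = "u", w = c("u", "v")))
    list(d1 = d1, d2 = d2,
         problem = EquivalenceProblem(dag, data1 = d1, data2 = d2,
                                      scoreKind = scoreKind),
         identity = c(u = "cu", v = "cv", w = "cw"))
  })
}

test_that("identity transfer reproduces the donor's own score", {
  fx <- renamedCopyProblem(1)
  expect_equal(scoreAssignment(fx$problem, fx$identity),
               bicScore(fx$d1, fx$problem@structure), tolerance = 1e-10)
})

test_that("assignment scoring enforces its preconditions", {
  fx <- renamedCopyProblem(2)
  expect_error(scoreAssignment(fx$problem, c(u = "cu", v = "cv")),
               "cover every slot")
  expect_error(scoreAssignment(fx$problem, c(u = "cu", v = "cu", w = "cw")),
               "injective")
  # arity mismatch is named
  d2 <- fx$d2
  rec <- cbind(stateRecords(d2), bad = rep(1:2, 20))
  d2b <- DiscreteDataset(rec, c(arities(d2), bad = 2L))
  pr <- EquivalenceProblem(fx$problem@structure, data1 = fx$d1, data2 = d2b)
  expect_error(scoreAssignment(pr, c(u = "cu", v = "bad", w = "cw")),
               "arity mismatch")
})

test_that("exchangeable slots score identically under permutation", {
  # two pure-noise leaf slots with a common parent are exchangeable
  funcEquiv:::withSeed(3, {
    rec <- cbind(p = sample.int(2L, 30, TRUE), q = sample.int(2L, 30, TRUE),
                 r = sample.int(2L, 30, TRUE))
    d <- DiscreteDataset(rec, setNames(rep(2L, 3), colnames(rec)))
    dag <- DAGStructure(c("s1", "s2", "s3"), list(s2 = "s1", s3 = "s1"))
    pr <- EquivalenceProblem(dag, slotArities = c(s1 = 2L, s2 = 2L, s3 = 2L),
                             data2 = d)
    a1 <- scoreAssignment(pr, c(s1 = "p", s2 = "q", s3 = "r"))
    a2 <- scoreAssignment(pr, c(s1 = "p", s2 = "r", s3 = "q"))
    expect_equal(a1, a2, tolerance = 1e-12)
  })
})

test_that("the acceptance rule follows its definition exactly", {
  expect_true(acceptMove(0, t = 1e-9, u = 0.999999))
  expect_true(acceptMove(5, t = 1, u = 0.99))
  expect_false(acceptMove(-1e6, t = 1e-6, u = 1 - 1e-12))  # underflow-safe
  expect_identical(acceptMove(-2, t = 4, u = exp(-0.5) - 1e-9), TRUE)
  expect_identical(acceptMove(-2, t = 4, u = exp(-0.5) + 1e-9), FALSE)
  expect_error(acceptMove(-1, t = 0, u = 0.5), "positive")
})

test_that("geometric cooling with a floor", {
  expect_equal(updateTemperature(1000), 900)
  t <- 1000
  for (i in 1:10) t <- updateTemperature(t)
  expect_equal(t, 1000 * 0.9^10, tolerance = 1e-12)
  expect_equal(updateTemperature(1e-13), 1e-12)
})

test_that("annealing search is seed-reproducible end to end", {
  fx <- renamedCopyProblem(4)
  sch <- annealingSchedule(iterations = 200, seed = 11)
  r1 <- functionalEquivalenceSearch(fx$problem, sch)
  r2 <- functionalEquivalenceSearch(fx$problem, sch)
  expect_identical(assignment(r1), assignment(r2))
  expect_identical(r1@trace, r2@trace)
  expect_identical(bestAssignment(r1), bestAssignment(r2))
  # best-ever dominates every accepted score along the trace
  expect_true(all(r1@bestScore >= r1@trace - 1e-12))
  expect_length(r1@trace, 200L)
})

test_that("constant-score landscapes accept every proposal", {
  # all columns identical: every assignment scores the same, dscore = 0
  rec <- matrix(rep(rep(1:2, 15), 4), ncol = 4)
  colnames(rec) <- c("a1", "a2", "a3", "a4")
  d <- DiscreteDataset(rec, setNames(rep(2L, 4), colnames(rec)))
  dag <- DAGStructure(c("s1", "s2"), list(s2 = "s1"))
  pr <- EquivalenceProblem(dag, slotArities = c(s1 = 2L, s2 = 2L), data2 = d)
  res <- functionalEquivalenceSearch(pr, annealingSchedule(iterations = 100,
                                                           seed = 5))
  expect_equal(res@accepted, 100L)
  expect_true(all(res@trace == res@trace[1]))
})

test_that("with a cold start the search never accepts a downhill move", {
  fx <- renamedCopyProblem(6)
  sch <- annealingSchedule(tStart = 1e-12, iterations = 300, seed = 7)
  res <- functionalEquivalenceSearch(fx$problem, sch)
  expect_true(all(diff(res@trace) >= -1e-12))
})

test_that("the search attains the exhaustive optimum on a renamed copy", {
  hits <- vapply(1:10, function(s) {
    fx <- renamedCopyProblem(20 + s, nDistract = 3)
    enum <- enumerateAssignments(fx$problem)
    res <- functionalEquivalenceSearch(fx$problem,
                                       annealingSchedule(seed = s))
    abs(res@bestScore - max(enum$scores)) < 1e-9
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # and the identity score is attained when data2 is a renamed copy
  fx <- renamedCopyProblem(31)
  res <- functionalEquivalenceSearch(fx$problem, annealingSchedule(seed = 1))
  expect_gte(res@bestScore + 1e-9,
             scoreAssignment(fx$problem, fx$identity))
})

test_that("transfer scoring pins the identity on a renamed copy", {
  fx <- renamedCopyProblem(8, scoreKind = "transfer")
  best <- enumerateAssignments(fx$problem)
  top <- best$assignments[best$best, ]
  expect_identical(unname(top), unname(fx$identity[colnames(best$assignments)]))
})

test_that("results serialize to JSON and CSV", {
  fx <- renamedCopyProblem(9)
  res <- functionalEquivalenceSearch(fx$problem,
                                     annealingSchedule(iterations = 50,
                                                       seed = 2))
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  writeEquivalenceResult(res, fj, fc)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$bestScore, res@bestScore)
  expect_equal(nrow(read.csv(fc)), length(bestAssignment(res)))
})
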