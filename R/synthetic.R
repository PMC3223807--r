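# Synthetic multi-region community generator.
#
# The generator emulates the statistical structure the inference assumes: a
# small set of "core" species realising a shared functional structure (one
# target species driven by two prey-like cores, all cores attracted to
# regime-dependent levels), plus independent autocorrelated distractors.
# The regime shift is a CPT switch at the collapse year -- a step change in
# the dependence structure, not merely a mean shift of the target -- and the
# true latent state is the pre/post indicator.  Discrete states are emitted
# as continuous biomass through a per-state lognormal layer so the full
# read -> discretize -> analyse path is exercised.

#' Describe a synthetic two-region scenario
#'
#' Defaults are sized to the motivating surveys: 45 annual samples starting
#' 1963, collapse years 1988 (region A) and 1992 (region B), about 20
#' species per region of which 5 are core.  `collapseYearB = NA` produces a
#' no-collapse region (a North-Sea analogue) whose true latent trajectory is
#' constant.
#'
#' @param nCore number of core species (>= 2; slot 1 is the target).
#' @param nDistractors independent distractor species per region.
#' @param nYears,startYear length and first calendar year of the series.
#' @param collapseYearA,collapseYearB collapse years (B may be `NA`).
#' @param nStates states per species in the generating model.
#' @param noise probability mass spread off the model-preferred state
#'   (moderate survey noise at the default 0.15).
#' @param persistence weight on staying in the previous state (cores).
#' @param logSpacing log-biomass separation between adjacent states.
#' @param sdLog lognormal observation noise around the state mean.
#' @return a validated scenario list for [generateRegionPair()].
#' @export
syntheticScenario <- function(nCore = 5L, nDistractors = 15L, nYears = 45L,
                              startYear = 1963L, collapseYearA = 1988L,
                              collapseYearB = 1992L, nStates = 3L,
                              noise = 0.08, persistence = 0.55,
                              logSpacing = 1.5, sdLog = 0.3) {
  stopIfNot(nCore >= 2L, "at least 2 core species required")
  stopIfNot(nStates >= 2L, "nStates must be >= 2")
  stopIfNot(noise > 0 && noise < 1, "noise must be in (0, 1)")
  years <- seq.int(startYear, length.out = nYears)
  for (cy in c(collapseYearA, if (!is.na(collapseYearB)) collapseYearB)) {
    stopIfNot(cy > min(years) && cy <= max(years),
              "collapse years must fall inside the year span")
  }
  list(nCore = as.integer(nCore), nDistractors = as.integer(nDistractors),
       nYears = as.integer(nYears), startYear = as.integer(startYear),
       collapseYearA = as.integer(collapseYearA),
       collapseYearB = if (is.na(collapseYearB)) NA_integer_
                       else as.integer(collapseYearB),
       nStates = as.integer(nStates), noise = noise,
       persistence = persistence, logSpacing = logSpacing, sdLog = sdLog)
}

# Core roles.  Core 2 is the regime-driven hub: attracted to the top
# state before the collapse and the bottom state after, with strong
# year-to-year persistence, so it fluctuates within each regime.  Core 3
# mirrors the hub with its own weaker persistence; core 1, the target,
# tracks the hub before the collapse and is pinned low after it (the
# step change in functional structure); core 4 mirrors the target with a
# little persistence of its own; core 5 blends cores 4 and 3; cores
# beyond 5 track their predecessor.  The within-year graph is the cycle
#    2 -> 1,  2 -> 3,  1 -> 4,  4 -> 5 <- 3 ,
# with self-lag persistence 0.5 / 0.35 on cores 2 / 3.  Three
# features make the roles identifiable to a refit-parameter
# (conditional-entropy) score on the two-slice data: the collider at core
# 5 breaks the cycle's rotational symmetry (no skeleton+immorality
# automorphism, so no exact score ties); the strictly decreasing
# persistence profile pins the rotation images apart temporally; and all
# couplings are monotone state maps, which a noisy per-species
# discretization degrades only locally (an off-by-one bin keeps most of
# the dependence, where a modular/XOR-style coupling would lose all of
# it).  Every core shifts at the collapse year -- hub and target fall,
# their mirrors rise -- which is what the class-node feature selection
# keys on.

# distribution concentrated on `level` with `strength`, rest spread evenly
.levelDist <- function(level, strength, nS) {
  p <- rep((1 - strength) / nS, nS)
  p[level] <- p[level] + strength
  p
}

# generating-CPT lookup shared with the calibration tests; parentStates
# must follow .coreParents(j) order; prevSelf is the core's own state in
# the previous year (NULL in year 1), used by the persistent cores 2 and 3
.coreDistribution <- function(scn, j, regime, prevSelf = NULL,
                              parentStates = NULL) {
  nS <- scn$nStates
  noise <- scn$noise
  inv <- function(s) nS + 1L - s
  mid <- function(a, b) as.integer(pmin(nS, pmax(1L, round((a + b) / 2))))
  persist <- function(level, attract, pers, leak) {
    p <- rep(leak / nS, nS)
    p[level] <- p[level] + attract
    if (is.null(prevSelf)) p[level] <- p[level] + pers
    else p[prevSelf] <- p[prevSelf] + pers
    p
  }
  # children mix a coupling to their parent(s), an *own* regime-attracted
  # level (so their collapse response is not fully screened by the parent
  # and the class-node wrapper can see it), and their own persistence;
  # the mixture weights are distinct per role
  mix <- function(coupleTo, wC, L, wR, wP) {
    p <- rep((1 - wC - wR - wP) / nS, nS)
    p[coupleTo] <- p[coupleTo] + wC
    p[L] <- p[L] + wR
    if (is.null(prevSelf)) p[L] <- p[L] + wP
    else p[prevSelf] <- p[prevSelf] + wP
    p
  }
  # A score that re-fits parameters is blind to state identities: it can
  # only see *how concentrated* each conditional is, never at which
  # state.  Roles are therefore given distinct scalar fingerprints --
  # regime-conditional concentration, persistence, and coupling strength
  # ladders -- rather than distinct level patterns (which are invisible
  # to the fit).  Every core still shifts at the collapse because its
  # attraction level flips with the regime.
  lv <- function(pre, post) if (regime == 2L) post else pre
  if (j == 1L) {
    # the target: locked hard to the regime before and after the collapse
    if (regime == 2L) return(.levelDist(1L, 1 - noise, nS))
    return(mix(parentStates[1L], 0.10, nS, 0.82, 0))
  }
  if (j == 2L) {
    # the persistent hub: weak lock, strong memory; declines to the
    # middle state (not the bottom), unlike the fully collapsing target
    return(persist(lv(nS, 2L), 1 - scn$persistence - noise,
                   scn$persistence, noise))
  }
  if (j == 3L) {
    # firm lock, no memory, faint mirror coupling
    return(mix(inv(parentStates[1L]), 0.08, lv(1L, nS), 0.72, 0))
  }
  if (j == 4L) {
    # the coupled mirror: strong instantaneous coupling, mid-level lock
    return(mix(inv(parentStates[1L]), 0.40, lv(1L, 2L), 0.40, 0))
  }
  if (j == 5L) {
    # the blend: middling lock and coupling, two parents, distinct levels
    return(mix(mid(parentStates[1L], parentStates[2L]), 0.30,
               lv(2L, nS), 0.47, 0.08))
  }
  mix(parentStates[1L], 0.30, lv(1L, nS), 0.35, 0.20)
}

# within-year generating parents of core j (integer(0) = root)
.coreParents <- function(j) {
  switch(as.character(j),
         "1" = 2L, "2" = integer(0), "3" = 2L, "4" = 1L,
         "5" = c(4L, 3L), as.integer(j - 1L))
}

# one region's discrete core + distractor states; regime = 1/2 per year
.simRegion <- function(scn, regime) {
  nS <- scn$nStates
  nY <- scn$nYears
  core <- matrix(0L, nY, scn$nCore)
  pick <- function(p) sample.int(nS, 1L, prob = p)
  simOrder <- c(2L, 3L, 1L, setdiff(seq_len(scn$nCore), 1:3))
  simOrder <- simOrder[simOrder <= scn$nCore]
  for (t in seq_len(nY)) {
    for (j in simOrder) {
      pj <- .coreParents(j)
      pj <- pj[pj <= scn$nCore]
      core[t, j] <- pick(.coreDistribution(
        scn, j, regime[t],
        prevSelf = if (t > 1L) core[t - 1L, j] else NULL,
        parentStates = if (length(pj)) core[t, pj] else NULL))
    }
  }
  distract <- matrix(0L, nY, scn$nDistractors)
  if (scn$nDistractors > 0L) {
    for (j in seq_len(scn$nDistractors)) {
      for (t in seq_len(nY)) {
        p <- rep(0.75 / nS, nS)
        if (t > 1L) p[distract[t - 1L, j]] <- p[distract[t - 1L, j]] + 0.25
        distract[t, j] <- pick(p / sum(p))
      }
    }
  }
  cbind(core, distract)
}

# lognormal emission: per-species base level, states spaced on the log scale
.emitBiomass <- function(states, scn) {
  nSp <- ncol(states)
  base <- rnorm(nSp, mean = log(100), sd = 1)
  mid <- (scn$nStates + 1) / 2
  vals <- matrix(0, nrow(states), nSp)
  for (j in seq_len(nSp)) {
    vals[, j] <- exp(base[j] + scn$logSpacing * (states[, j] - mid) +
                       rnorm(nrow(states), sd = scn$sdLog))
  }
  vals
}

#' Generate a matched pair of synthetic regions
#'
#' Region A and region B realise the same core functional structure with
#' independent randomness, their own collapse years and different species
#' labels: region B's columns are shuffled and renamed, so the slot ->
#' species correspondence is hidden.  Ground truth (mapping, per-year latent
#' regime, true within-year dependence edges, discrete state matrices) is
#' returned alongside.
#'
#' @param scenario a [syntheticScenario()] list.
#' @param seed integer seed; the whole pair is bit-reproducible.
#' @return list with `regionA`, `regionB` ([BiomassTable-class]) and
#'   `truth`: `mapping` (A core species -> B species), `coreA`, `coreB`,
#'   `target`, `targetB`, `hiddenA`, `hiddenB` (1 = baseline, 2 =
#'   collapsed), `years`, `trueEdges` (within-year prey -> target),
#'   `statesA`, `statesB`.
#' @export
generateRegionPair <- function(scenario, seed = 1L) {
  scn <- scenario
  years <- seq.int(scn$startYear, length.out = scn$nYears)
  regimeA <- ifelse(years >= scn$collapseYearA, 2L, 1L)
  regimeB <- if (is.na(scn$collapseYearB)) rep(1L, scn$nYears)
             else ifelse(years >= scn$collapseYearB, 2L, 1L)
  nSp <- scn$nCore + scn$nDistractors
  withSeed(seed, {
    statesA <- .simRegion(scn, regimeA)
    statesB <- .simRegion(scn, regimeB)
    valsA <- .emitBiomass(statesA, scn)
    valsB <- .emitBiomass(statesB, scn)
    spA <- sprintf("spA%02d", seq_len(nSp))
    spB <- sprintf("spB%02d", seq_len(nSp))
    # published column p of region B shows simulated column ord[p]
    # (simulation order puts the core slots first), hiding the slot roles
    ord <- sample.int(nSp)
    posOf <- match(seq_len(nSp), ord)
    regionA <- BiomassTable(valsA, years, spA, regionId = "A")
    regionB <- BiomassTable(valsB[, ord, drop = FALSE], years, spB,
                            regionId = "B")
    coreA <- spA[seq_len(scn$nCore)]
    coreB <- spB[posOf[seq_len(scn$nCore)]]
    edges <- do.call(rbind, lapply(seq_len(scn$nCore), function(j) {
      pj <- .coreParents(j)
      pj <- pj[pj <= scn$nCore]
      if (length(pj)) cbind(parent = coreA[pj], child = coreA[j]) else NULL
    }))
    truth <- list(mapping = setNames(coreB, coreA), coreA = coreA,
                  coreB = coreB, target = coreA[1L], targetB = coreB[1L],
                  hiddenA = regimeA, hiddenB = regimeB, years = years,
                  trueEdges = edges,
                  statesA = `colnames<-`(statesA, spA),
                  statesB = `colnames<-`(statesB[, ord, drop = FALSE], spB))
    list(regionA = regionA, regionB = regionB, truth = truth)
  })
}

#' Sample a single-region series from an explicit CPT switch
#'
#' Small sampler for latent-chain tests: each variable depends only on its
#' own previous state through `preCPT` before the collapse year and
#' `postCPT` from it onward.  The true latent state is the pre/post
#' indicator.
#'
#' @param nYears,startYear series length and first year.
#' @param collapseYear year of the CPT switch; beyond the span means no
#'   switch ever happens.
#' @param preCPT,postCPT named lists of row-stochastic `r x r` matrices
#'   (row = previous state), one per variable.
#' @param seed integer seed.
#' @return list with `dataset` ([DiscreteDataset-class]), `years` and
#'   `states` (true regime per year, 1 = pre, 2 = post).
#' @export
generateRegimeShiftSeries <- function(nYears, collapseYear, preCPT, postCPT,
                                      startYear = 1963L, seed = 1L) {
  stopIfNot(identical(names(preCPT), names(postCPT)),
            "pre/post CPTs must cover the same variables")
  years <- seq.int(startYear, length.out = nYears)
  states <- ifelse(years >= collapseYear, 2L, 1L)
  withSeed(seed, {
    rec <- sapply(names(preCPT), function(v) {
      r <- nrow(preCPT[[v]])
      x <- integer(nYears)
      x[1] <- sample.int(r, 1L)
      for (t in seq_len(nYears)[-1]) {
        cpt <- if (states[t] == 2L) postCPT[[v]] else preCPT[[v]]
        x[t] <- sample.int(r, 1L, prob = cpt[x[t - 1L], ])
      }
      x
    })
    list(dataset = DiscreteDataset(rec), years = years, states = states)
  })
}

#' Recovery metrics against ground truth
#'
#' Dispatches on the result type: an [EquivalenceResult-class] yields the
#' mapping recovery fraction (correctly assigned core slots over the number
#' of core slots; unselected cores count as wrong); a prediction
#' `data.frame` (from [predictOneStep()] / [transferModel()]) yields the
#' latent-state accuracy after majority label alignment and the one-step
#' prediction accuracy; a [DAGStructure-class] yields edge precision/recall
#' against `truth$trueEdges` (direction ignored, since greedy-search edge
#' direction is order-determined).
#'
#' @param result the object to evaluate.
#' @param truth the `truth` list of [generateRegionPair()] (or one with the
#'   matching fields).
#' @return named list of metrics, all in `[0, 1]`.
#' @export
evaluateRecovery <- function(result, truth) {
  if (is(result, "EquivalenceResult")) {
    a <- bestAssignment(result)
    hit <- vapply(truth$coreA, function(s)
      !is.na(a[s]) && identical(unname(a[s]), unname(truth$mapping[[s]])),
      TRUE)
    return(list(mappingRecovery = sum(hit) / length(truth$coreA)))
  }
  if (is.data.frame(result)) {
    tru <- truth$hiddenB %||% truth$hiddenA
    idx <- match(result$year, truth$years)
    tru <- tru[idx]
    raw <- mean(result$mapState == tru)
    return(list(hiddenAccuracy = max(raw, 1 - raw),
                oneStepAccuracy = mean(result$predicted == result$observed)))
  }
  if (is(result, "DAGStructure")) {
    und <- function(e) if (nrow(e)) apply(e, 1, function(r)
      paste(sort(r), collapse = "~")) else character(0)
    got <- und(edgeList(result))
    want <- und(truth$trueEdges)
    tp <- length(intersect(got, want))
    return(list(edgePrecision = if (length(got)) tp / length(got) else 1,
                edgeRecall = if (length(want)) tp / length(want) else 1))
  }
  stop("unsupported result type", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a regime shift in a MAP latent path
#'
#' The detected switch year is the start of the terminal run of the
#' collapsed state (state 2); `postStability` is the fraction of years at or
#' after `collapseYear` spent in state 2.
#'
#' @param mapState integer MAP path (1/2).
#' @param years matching calendar years.
#' @param collapseYear reference collapse year for the stability fraction.
#' @return list with `switchYear` (`NA` if the path does not end collapsed)
#'   and `postStability`.
#' @export
detectRegimeShift <- function(mapState, years, collapseYear) {
  n <- length(mapState)
  switchYear <- NA_integer_
  if (mapState[n] == 2L) {
    i <- n
    while (i > 1L && mapState[i - 1L] == 2L) i <- i - 1L
    switchYear <- years[i]
  }
  post <- years >= collapseYear
  list(switchYear = switchYear,
       postStability = if (any(post)) mean(mapState[post] == 2L) else NA_real_)
}
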