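#' Define a functional-equivalence search problem
#'
#' Packages the donor network (a structure learned in region 1, with the
#' arities its discretization produced) together with the candidate dataset
#' of region 2.  The search looks for the injective assignment of region-2
#' species to the donor "slots" (donor species names) under which the donor
#' structure best fits the region-2 data.
#'
#' The donor may be a plain within-year network, or a two-slice network
#' whose lagged nodes carry the suffix `".lag"` (see
#' [flattenTransitions()]); in the latter case a slot and its lag twin are
#' assigned together, so the fit is judged on the dependence structure and
#' the year-to-year dynamics at once, which pins functional roles far more
#' sharply than the within-year dependence alone.
#'
#' @param structure donor [DAGStructure-class]; its node names are the slots.
#' @param data1 the donor [DiscreteDataset-class] (used only for the slot
#'   arities); alternatively supply `slotArities` directly.
#' @param data2 [DiscreteDataset-class] of the second region.
#' @param pool candidate species of `data2` (default: all its variables
#'   that are not lag twins or fixed columns).
#' @param fixed named character vector of donor nodes bound to fixed
#'   `data2` columns (e.g. `c(collapse = "collapse")` to anchor the donor's
#'   class node to the target region's own collapse labelling); these slots
#'   are never reassigned.
#' @param scoreKind `"bic"` (default, the complexity-penalised fit with
#'   parameters re-fit on `data2`), `"k2"` (Cooper-Herskovits joint score on
#'   `data2`), or `"transfer"`: the log-likelihood of `data2` under the
#'   *donor-parametrized* model, i.e. Laplace tables fit on `data1` and
#'   carried over.  Re-fit scores judge only how concentrated each
#'   conditional is -- they are invariant to per-variable state
#'   relabelings -- whereas the transfer score also demands that the
#'   states themselves behave as they did in the donor region, which pins
#'   functional roles far more sharply on series this short.
#' @param slotArities named integer arities per slot, overriding `data1`.
#' @return an [EquivalenceProblem-class].
#' @seealso [functionalEquivalenceSearch()], [scoreAssignment()]
#' @export
EquivalenceProblem <- function(structure, data1 = NULL, data2,
                               pool = NULL, fixed = character(0),
                               scoreKind = c("bic", "k2", "transfer"),
                               slotArities = NULL) {
  scoreKind <- match.arg(scoreKind)
  if (is.null(pool)) {
    pool <- grep("\\.lag$", variableNames(data2), invert = TRUE,
                 value = TRUE)
    pool <- setdiff(pool, fixed)
  }
  if (is.null(slotArities)) {
    stopIfNot(!is.null(data1), "supply data1 or slotArities")
    slotArities <- arities(data1)[structure@nodes]
  }
  cpts <- if (scoreKind == "transfer") {
    stopIfNot(!is.null(data1), "transfer scoring requires data1")
    fitParameters(data1, structure, "laplace")
  } else {
    new("CPTSet", tables = list(), estimator = "laplace",
        arities = integer(0))
  }
  new("EquivalenceProblem", structure = structure,
      slotArities = slotArities[structure@nodes], data2 = data2,
      pool = pool, fixed = fixed, scoreKind = scoreKind, donorCPTs = cpts)
}

setMethod("show", "EquivalenceProblem", function(object) {
  cat(sprintf("EquivalenceProblem (%s): %d slots, pool of %d candidates\n",
              object@scoreKind, length(slotNames(object)),
              length(object@pool)))
})

#' Assignable slots of an equivalence problem
#'
#' The donor structure's nodes minus any `".lag"` twins (which follow their
#' unlagged slot automatically) and minus the fixed slots.
#'
#' @param problem an [EquivalenceProblem-class].
#' @return character vector of slot names.
#' @export
slotNames <- function(problem) {
  free <- grep("\\.lag$", problem@structure@nodes, invert = TRUE,
               value = TRUE)
  setdiff(free, names(problem@fixed))
}

# merge the fixed slots and expand over the .lag twins
.expandAssignment <- function(problem, vars2) {
  vars2 <- c(vars2, problem@fixed)
  lagged <- grep("\\.lag$", problem@structure@nodes, value = TRUE)
  if (length(lagged)) {
    base <- sub("\\.lag$", "", lagged)
    vars2 <- c(vars2, setNames(paste0(unname(vars2[base]), ".lag"), lagged))
  }
  vars2
}

#' Score one slot assignment
#'
#' Relabels the donor structure onto the assigned region-2 columns and
#' scores that fixed structure on the region-2 data: BIC with parameters
#' re-fit by maximum likelihood (default), or the K2 joint score.  Higher is
#' better.  Assigned columns must match the slot arities of the donor
#' discretization.
#'
#' @param problem an [EquivalenceProblem-class].
#' @param vars2 named character vector, slot -> assigned region-2 species;
#'   must be injective and cover every slot (lag twins follow their slot).
#' @return the score (log space).
#' @export
scoreAssignment <- function(problem, vars2) {
  stopIfNot(all(slotNames(problem) %in% names(vars2)),
            "assignment must cover every slot")
  stopIfNot(!anyDuplicated(vars2[slotNames(problem)]),
            "assignment must be injective")
  stopIfNot(all(vars2[slotNames(problem)] %in% problem@pool),
            "assigned species outside the pool")
  slots <- problem@structure@nodes
  vars2 <- .expandAssignment(problem, vars2[slotNames(problem)])[slots]
  ar2 <- arities(problem@data2)[vars2]
  bad <- which(unname(ar2) != unname(problem@slotArities))
  if (length(bad)) {
    stop(sprintf("arity mismatch: slot '%s' (r=%d) vs species '%s' (r=%d)",
                 slots[bad[1]], problem@slotArities[[bad[1]]],
                 vars2[[bad[1]]], ar2[[bad[1]]]), call. = FALSE)
  }
  sum(.familyScores(problem, vars2))
}

# per-family (child-node) score terms of an already-expanded assignment
.familyScores <- function(problem, vars2) {
  ds <- subsetVariables(problem@data2, unname(vars2))
  rec <- stateRecords(ds)
  colnames(rec) <- names(vars2)
  ar <- setNames(arities(ds), names(vars2))
  kind <- problem@scoreKind
  dag <- problem@structure
  if (kind == "transfer") {
    return(vapply(setNames(dag@nodes, dag@nodes), function(v) {
      th <- problem@donorCPTs@tables[[v]]
      pa <- dag@parents[[v]]
      j <- configIndex(rec[, pa, drop = FALSE], unname(ar[pa]))
      sum(log(th[cbind(j, rec[, v])]))
    }, 0))
  }
  vapply(setNames(dag@nodes, dag@nodes), function(v)
    .familyScoreC(rec, match(v, colnames(rec)),
                  match(dag@parents[[v]], colnames(rec)), ar, kind), 0)
}

#' Annealing acceptance rule
#'
#' Accept iff `dscore >= 0` or `u < exp(dscore / t)`.  Uphill and sideways
#' moves are always taken; downhill moves survive with the Boltzmann
#' probability, which underflows safely to 0 for very poor moves at low
#' temperature.
#'
#' @param dscore proposed score minus current score.
#' @param t current temperature, strictly positive.
#' @param u a uniform draw in `[0, 1)`.
#' @return logical.
#' @export
acceptMove <- function(dscore, t, u) {
  stopIfNot(t > 0, "temperature must be positive")
  dscore >= 0 || u < exp(dscore / t)
}

#' Geometric cooling step
#'
#' @param t current temperature.
#' @param coolingFactor multiplicative factor in (0, 1), default 0.9.
#' @param floor lower clamp (default `1e-12`) so late iterations degrade to
#'   greedy hill-climbing instead of dividing by zero.
#' @return the cooled temperature, `max(t * coolingFactor, floor)`.
#' @export
updateTemperature <- function(t, coolingFactor = 0.9, floor = 1e-12) {
  stopIfNot(t > 0, "temperature must be positive")
  max(t * coolingFactor, floor)
}

#' Annealing schedule
#'
#' Defaults follow the search's published setting: `iterations = 1000`,
#' `tStart = 1000`, cooling factor 0.9 applied once per iteration.
#'
#' @param tStart initial temperature.
#' @param iterations number of proposal iterations.
#' @param coolingFactor geometric cooling factor in (0, 1).
#' @param seed RNG seed for the whole search.
#' @return a list used by [functionalEquivalenceSearch()].
#' @export
annealingSchedule <- function(tStart = 1000, iterations = 1000L,
                              coolingFactor = 0.9, seed = 1L) {
  stopIfNot(tStart > 0, "tStart must be positive")
  stopIfNot(iterations >= 1L, "iterations must be >= 1")
  stopIfNot(coolingFactor > 0 && coolingFactor < 1,
            "coolingFactor must be in (0, 1)")
  list(tStart = tStart, iterations = as.integer(iterations),
       coolingFactor = coolingFactor, seed = as.integer(seed))
}

#' Simulated-annealing search for functionally equivalent species
#'
#' Starts from a random injective assignment of pool species to the donor
#' slots.  Each iteration randomly replaces one selected variable: a slot
#' is drawn (half the time uniformly, half the time the slot whose
#' families currently fit worst, which concentrates moves where the
#' assignment is weakest), together with a uniformly drawn candidate
#' species (any pool member other than the slot's current one).  An unused
#' candidate simply replaces the slot's species, while a candidate
#' currently held by another slot exchanges the two slots' species, so the
#' assignment stays injective and permutations of the selected species
#' remain reachable late in the schedule (with replace-by-unused moves
#' only, a pairwise slot exchange can never be repaired once the
#' temperature is low).  Each proposal is rescored, accepted by
#' [acceptMove()] (undone on rejection), and the temperature is cooled
#' geometrically.  The returned object carries both the final assignment
#' (the algorithm's raw output) and the best-ever assignment, which is the
#' recommended one.
#'
#' @param problem an [EquivalenceProblem-class].
#' @param schedule an [annealingSchedule()] list.
#' @return an [EquivalenceResult-class]; the per-iteration trace records the
#'   current score after each accept/reject decision.
#' @export
functionalEquivalenceSearch <- function(problem,
                                        schedule = annealingSchedule()) {
  slots <- slotNames(problem)
  nS <- length(slots)
  pool <- problem@pool
  stopIfNot(length(pool) >= nS, "candidate pool smaller than the slot count")
  withSeed(schedule$seed, {
    vars2 <- setNames(sample(pool, nS), slots)
    score <- scoreAssignment(problem, vars2)
    bestV <- vars2
    bestS <- score
    t <- schedule$tStart
    trace <- numeric(schedule$iterations)
    acc <- 0L
    # families each slot participates in (child or parent, lag included),
    # used to focus proposals on the slot currently fitting worst
    involvement <- lapply(setNames(slots, slots), function(s) {
      nm <- c(s, paste0(s, ".lag"))
      vapply(problem@structure@nodes, function(v)
        v %in% nm || any(problem@structure@parents[[v]] %in% nm), TRUE)
    })
    slotResp <- function(a) {
      fs <- .familyScores(problem, .expandAssignment(problem, a))
      vapply(involvement, function(m) sum(fs[m]), 0)
    }
    for (i in seq_len(schedule$iterations)) {
      # half the proposals target the worst-fitting slot, half explore
      slot <- if (runif(1L) < 0.5) slots[which.min(slotResp(vars2))]
              else slots[sample.int(nS, 1L)]
      others <- setdiff(pool, vars2[[slot]])
      cand <- others[sample.int(length(others), 1L)]
      holder <- names(vars2)[match(cand, vars2)]   # NA when cand is unused
      old <- vars2[[slot]]
      vars2[[slot]] <- cand
      if (!is.na(holder)) vars2[[holder]] <- old
      rescore <- scoreAssignment(problem, vars2)
      u <- runif(1L)
      if (acceptMove(rescore - score, t, u)) {
        score <- rescore
        acc <- acc + 1L
        if (rescore > bestS) {
          bestS <- rescore
          bestV <- vars2
        }
      } else {
        vars2[[slot]] <- old
        if (!is.na(holder)) vars2[[holder]] <- cand
      }
      t <- updateTemperature(t, schedule$coolingFactor)
      trace[i] <- score
    }
    new("EquivalenceResult", assignment = vars2, finalScore = score,
        bestAssignment = bestV, bestScore = bestS, trace = trace,
        accepted = acc, schedule = schedule)
  })
}

#' @rdname accessors
#' @export
setMethod("assignment", "EquivalenceResult", function(x) x@assignment)
#' @rdname accessors
#' @export
setMethod("bestAssignment", "EquivalenceResult", function(x) x@bestAssignment)

setMethod("show", "EquivalenceResult", function(object) {
  cat(sprintf(
    "EquivalenceResult: %d slots, best score %.4f (final %.4f), %d/%d moves accepted\n",
    length(object@assignment), object@bestScore, object@finalScore,
    object@accepted, length(object@trace)))
  m <- head(seq_along(object@bestAssignment), 8L)
  cat(paste0("  ", names(object@bestAssignment)[m], " <- ",
             object@bestAssignment[m], collapse = "\n"), "\n")
})

#' Exhaustively score every injective assignment
#'
#' Brute-force reference for small candidate pools: enumerates all injective
#' slot assignments and returns them with their scores.
#'
#' @param problem an [EquivalenceProblem-class]; feasible for pools of up to
#'   about 8 candidates.
#' @return list with `assignments` (matrix, one row per assignment) and
#'   `scores`; `best` gives the index of the optimum.
#' @export
enumerateAssignments <- function(problem) {
  slots <- slotNames(problem)
  pool <- problem@pool
  perm <- function(v, k) {
    if (k == 0L) return(list(character(0)))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm(v[-i], k - 1L)) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  all <- perm(pool, length(slots))
  scores <- vapply(all, function(a)
    scoreAssignment(problem, setNames(a, slots)), 0)
  mat <- do.call(rbind, all)
  colnames(mat) <- slots
  list(assignments = mat, scores = scores, best = which.max(scores))
}

#' Export an equivalence result
#'
#' Writes the mapping, both scores and the full trace as JSON, and the
#' best-ever assignment as a two-column CSV (`slot_species`,
#' `assigned_species`).
#'
#' @param result an [EquivalenceResult-class].
#' @param jsonFile,csvFile output paths (either may be `NULL` to skip).
#' @return invisibly, the list written to JSON.
#' @export
writeEquivalenceResult <- function(result, jsonFile = NULL, csvFile = NULL) {
  out <- list(assignment = as.list(result@assignment),
              finalScore = result@finalScore,
              bestAssignment = as.list(result@bestAssignment),
              bestScore = result@bestScore,
              accepted = result@accepted,
              schedule = result@schedule,
              trace = result@trace)
  if (!is.null(jsonFile)) {
    jsonlite::write_json(out, jsonFile, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvFile)) {
    write.csv(data.frame(slot_species = names(result@bestAssignment),
                         assigned_species = unname(result@bestAssignment)),
              csvFile, row.names = FALSE)
  }
  invisible(out)
}
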