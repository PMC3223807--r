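#' Run the full cross-region transfer workflow
#'
#' Chains the four stages on a pair of biomass tables: discretize and label
#' region A, bootstrap-wrapper select the collapse-relevant species, learn a
#' two-slice donor network over them (within-year classifier structure plus
#' the inter-slice edges, with the collapse class node anchored), anneal the
#' functional-equivalence mapping into region B under the donor-parametrized
#' transfer score, fit the latent-regime DBN on region A, and transfer it
#' through the recovered mapping to predict region B one step ahead.
#'
#' Biomass is discretized with equal-width bins on the log scale by
#' default: survey biomass spans orders of magnitude, and fixed log-scale
#' bins let a persistent low or high regime keep its own state, where
#' equal-frequency bins would split it.  When `collapseYearB` is known the
#' donor keeps its collapse class node and region B's own labelling fills
#' that slot during scoring; with `collapseYearB = NULL` (a region with no
#' observed collapse) the donor is built without the class node.
#'
#' @param regionA,regionB [BiomassTable-class] objects.
#' @param collapseYearA collapse year of the donor region.
#' @param target the predicted (cod-like) species of region A; always kept
#'   in the selection.
#' @param collapseYearB collapse year of the target region, or `NULL` if
#'   none is assumed.
#' @param nBins discretization states (default 3).
#' @param method,transform passed to [discretizeBiomass()].
#' @param nBoot bootstrap resamples for the wrapper (default 200; the
#'   full-scale published setting is 1000).
#' @param nSelect how many top-ranked species to keep (default 7).
#'   Screening favours recall: a relevant species missed here is
#'   irrecoverable downstream, while an extra candidate merely widens the
#'   equivalence search.
#' @param maxParents parent cap for the structure searches.
#' @param scoreKind assignment score for the equivalence search; default
#'   `"transfer"` (see [EquivalenceProblem()]).
#' @param schedule [annealingSchedule()] for the equivalence search.
#' @param seed base seed for the bootstrap and EM stages.
#' @return list with `ranking`, `selected`, `donorStructure` (two-slice),
#'   `problem`, `equivalence` ([EquivalenceResult-class]), `model` (aligned
#'   [DBNModel-class]), `emReport`, `transfer` (prediction `data.frame` on
#'   region B), `datasetA`, `datasetB`.
#' @export
runTransferPipeline <- function(regionA, regionB, collapseYearA, target,
                                collapseYearB = NULL, nBins = 3L,
                                method = "equal_width", transform = "log",
                                nBoot = 200L, nSelect = 7L, maxParents = 3L,
                                scoreKind = "transfer",
                                schedule = annealingSchedule(seed = 1L),
                                seed = 1L) {
  dA <- discretizeBiomass(regionA, nBins = nBins, method = method,
                          transform = transform)
  yearsA <- sampleYears(regionA)
  labeled <- labelCollapse(dA, yearsA, collapseYearA)
  ranking <- wrapperSelect(labeled, nBoot = nBoot, seed = seed,
                           maxParents = maxParents)
  selected <- union(target, ranking$species[ranking$rank <= nSelect])
  ordA <- ranking$species[ranking$species %in% selected]
  dSel <- subsetVariables(dA, ordA)
  labSel <- labelCollapse(dSel, yearsA, collapseYearA)
  cls <- labSel@className
  useClass <- !is.null(collapseYearB)

  # two-slice donor: within-year (classifier) edges + inter-slice edges
  dAc <- withClassVariable(labSel)
  donorStatic <- if (useClass) {
    k2Search(dAc, nodeOrder = c(cls, ordA), maxParents = maxParents,
             scoreKind = "k2")
  } else {
    k2Search(dSel, nodeOrder = ordA, maxParents = maxParents,
             scoreKind = "k2")
  }
  tdataA <- makeTransitionDataset(dSel, yearsA)
  inter <- revealSearch(tdataA, maxParents = maxParents,
                        excludeSelf = target)
  donor <- DAGStructure(
    c(paste0(ordA, ".lag"), if (useClass) cls, ordA),
    setNames(c(if (useClass) list(character(0)),
               lapply(ordA, function(v)
                 c(donorStatic@parents[[v]], lagNames(inter[[v]])))),
             c(if (useClass) cls, ordA)))

  dB <- discretizeBiomass(regionB, nBins = nBins, method = method,
                          transform = transform)
  yearsB <- sampleYears(regionB)
  pool <- variableNames(dB)[arities(dB) == nBins]
  dBpool <- subsetVariables(dB, pool)
  flatA <- flattenTransitions(if (useClass) dAc else dSel, yearsA)
  flatB <- flattenTransitions(
    if (useClass) withClassVariable(labelCollapse(dBpool, yearsB,
                                                  collapseYearB))
    else dBpool, yearsB)
  problem <- EquivalenceProblem(donor, data1 = flatA, data2 = flatB,
                                pool = pool,
                                fixed = if (useClass) setNames(cls, cls)
                                        else character(0),
                                scoreKind = scoreKind)
  equivalence <- functionalEquivalenceSearch(problem, schedule)

  fit <- fitEM(dbnSkeleton(inter, target, arities(dSel), stateLabels(dSel)),
               tdataA, seed = seed,
               initStates = ifelse(tdataA@pairYears >= collapseYearA, 2L, 1L))
  model <- alignHiddenLabels(fit$model, dSel, yearsA, collapseYearA)
  transfer <- transferModel(model, equivalence, dB, yearsB)
  list(ranking = ranking, selected = selected, donorStructure = donor,
       problem = problem, equivalence = equivalence, model = model,
       emReport = fit$report, transfer = transfer, datasetA = dA,
       datasetB = dB)
}

#' Derange an assignment for a wrong-mapping baseline
#'
#' Permutes the assigned species among the slots so that no slot keeps its
#' original species (a derangement), giving the permuted-mapping baseline
#' that a faithful transfer should beat.
#'
#' @param mapping named character vector, slot -> species (length >= 2).
#' @param seed integer seed.
#' @return the deranged mapping.
#' @export
permuteAssignment <- function(mapping, seed = 1L) {
  n <- length(mapping)
  stopIfNot(n >= 2L, "need at least 2 slots to derange")
  withSeed(seed, {
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
    }
    setNames(unname(mapping)[p], names(mapping))
  })
}
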