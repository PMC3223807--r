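#' @import methods
NULL

#' BiomassTable: species-by-year biomass for one region
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"biomass"` with species as rows and survey years as columns.
#' The region label lives in `metadata(x)$regionId` and the calendar years in
#' `colData(x)$year` (strictly increasing; gaps allowed).
#'
#' @seealso [BiomassTable()], [readBiomassTable()], [discretizeBiomass()]
#' @export
setClass("BiomassTable", contains = "SummarizedExperiment")

setValidity("BiomassTable", function(object) {
  msg <- character()
  if (!"biomass" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'biomass' is required")
  else {
    v <- SummarizedExperiment::assay(object, "biomass")
    if (any(!is.finite(v))) msg <- c(msg, "biomass values must be finite")
    else if (any(v < 0)) msg <- c(msg, "biomass values must be non-negative")
  }
  yr <- SummarizedExperiment::colData(object)$year
  if (is.null(yr)) msg <- c(msg, "colData must contain a 'year' column")
  else {
    if (anyDuplicated(yr)) msg <- c(msg, "duplicate years")
    if (is.unsorted(yr, strictly = TRUE)) msg <- c(msg, "years must be strictly increasing")
  }
  sp <- rownames(object)
  if (is.null(sp) || anyDuplicated(sp)) msg <- c(msg, "species names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' DiscreteDataset: categorical records with per-variable arity
#'
#' The container all network scoring operates on: an M-by-n integer matrix of
#' state indices in `1..r_i` (column names are variable names), the per-variable
#' arities `r_i`, and ordered state labels per variable (for discretized
#' biomass these are the bin-edge intervals).
#'
#' @slot records integer matrix, one row per observation, states in `1..r_i`.
#' @slot arities named integer vector of state counts (each `>= 2`).
#' @slot stateLabels named list of ordered per-variable state labels.
#' @seealso [discretizeBiomass()], [bootstrapResample()]
#' @export
setClass("DiscreteDataset",
  representation(records = "matrix", arities = "integer", stateLabels = "list"))

setValidity("DiscreteDataset", function(object) {
  msg <- character()
  rec <- object@records
  ar <- object@arities
  if (nrow(rec) < 1L) msg <- c(msg, "at least one record is required")
  if (is.null(colnames(rec)) || anyDuplicated(colnames(rec)))
    msg <- c(msg, "records must have unique column names")
  if (!identical(colnames(rec), names(ar)))
    msg <- c(msg, "arities must be named after the record columns")
  if (any(ar < 2L)) msg <- c(msg, "every arity must be >= 2")
  if (!identical(names(object@stateLabels), names(ar)))
    msg <- c(msg, "stateLabels must be named after the record columns")
  else if (any(lengths(object@stateLabels) != ar))
    msg <- c(msg, "stateLabels lengths must match arities")
  if (length(msg) == 0L) {
    for (i in seq_len(ncol(rec))) {
      x <- rec[, i]
      if (anyNA(x) || any(x < 1L) || any(x > ar[i])) {
        msg <- c(msg, sprintf("states of '%s' outside 1..%d", colnames(rec)[i], ar[i]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClassLabeledDataset: records with a binary collapse class
#'
#' Wraps a [DiscreteDataset-class] together with a binary class (1 = pre,
#' 2 = post functional collapse), the calendar year of each record and the
#' collapse year the labelling was derived from.
#'
#' @slot base the underlying [DiscreteDataset-class].
#' @slot className name of the class variable (default `"collapse"`).
#' @slot classValues integer vector, 1 (pre) or 2 (post), one per record.
#' @slot years integer calendar year per record.
#' @slot collapseYear the year of the assumed step change; that year and later
#'   are labelled post.
#' @seealso [labelCollapse()]
#' @export
setClass("ClassLabeledDataset",
  representation(base = "DiscreteDataset", className = "character",
                 classValues = "integer", years = "integer",
                 collapseYear = "integer"))

setValidity("ClassLabeledDataset", function(object) {
  msg <- character()
  M <- nrow(object@base@records)
  if (length(object@classValues) != M) msg <- c(msg, "one class value per record required")
  if (!all(object@classValues %in% c(1L, 2L))) msg <- c(msg, "class must be binary (1/2)")
  if (length(object@years) != M) msg <- c(msg, "one year per record required")
  if (object@className %in% colnames(object@base@records))
    msg <- c(msg, "class name collides with a variable name")
  if (length(msg)) msg else TRUE
})

#' DAGStructure: directed acyclic network topology
#'
#' Parent sets per node plus the total node order used by the greedy K2
#' search.  Validity enforces acyclicity (edges must also respect no
#' self-loops and parent sets drawn from the node set).
#'
#' @slot nodes ordered character vector of node names.
#' @slot parents named list (one entry per node) of parent name vectors.
#' @slot nodeOrder permutation of `nodes`: the total order used by search.
#' @seealso [DAGStructure()], [k2Search()]
#' @export
setClass("DAGStructure",
  representation(nodes = "character", parents = "list", nodeOrder = "character"))

setValidity("DAGStructure", function(object) {
  msg <- character()
  nd <- object@nodes
  if (anyDuplicated(nd)) msg <- c(msg, "duplicate node names")
  if (!identical(names(object@parents), nd)) msg <- c(msg, "parents must be named after nodes")
  else {
    for (v in nd) {
      p <- object@parents[[v]]
      if (v %in% p) msg <- c(msg, sprintf("self-loop at '%s'", v))
      if (!all(p %in% nd)) msg <- c(msg, sprintf("unknown parent of '%s'", v))
      if (anyDuplicated(p)) msg <- c(msg, sprintf("duplicate parents of '%s'", v))
    }
  }
  if (!setequal(object@nodeOrder, nd) || length(object@nodeOrder) != length(nd))
    msg <- c(msg, "nodeOrder must be a permutation of nodes")
  if (length(msg) == 0L && is.null(topoSort(object@parents)))
    msg <- c(msg, "graph contains a directed cycle")
  if (length(msg)) msg else TRUE
})

#' CPTSet: conditional probability tables for a DAG
#'
#' One row-stochastic table per node over (parent instantiation, child state).
#' Each table is a `q_i` x `r_i` matrix whose rows index linearised parent
#' configurations (first parent fastest) and carries attributes `parents` and
#' `parentArities`.
#'
#' @slot tables named list of `q_i x r_i` stochastic matrices.
#' @slot estimator `"mle"` or `"laplace"`.
#' @slot arities named integer vector of child arities.
#' @seealso [fitParameters()], [dimG()]
#' @export
setClass("CPTSet",
  representation(tables = "list", estimator = "character", arities = "integer"))

setValidity("CPTSet", function(object) {
  msg <- character()
  for (v in names(object@tables)) {
    tab <- object@tables[[v]]
    if (ncol(tab) != object@arities[[v]]) msg <- c(msg, sprintf("arity mismatch at '%s'", v))
    if (any(abs(rowSums(tab) - 1) > 1e-12)) msg <- c(msg, sprintf("rows of '%s' must sum to 1", v))
  }
  if (!object@estimator %in% c("mle", "laplace")) msg <- c(msg, "unknown estimator")
  if (length(msg)) msg else TRUE
})

#' ScoredNetwork: a structure with its network score
#'
#' @slot structure the scored [DAGStructure-class].
#' @slot scoreValue log-space score.
#' @slot scoreKind `"k2"` or `"bic"`.
#' @slot priorC the constant structure prior `c` (K2 joint score only).
#' @export
setClass("ScoredNetwork",
  representation(structure = "DAGStructure", scoreValue = "numeric",
                 scoreKind = "character", priorC = "numeric"))

#' EquivalenceProblem: inputs of the functional-equivalence search
#'
#' The donor network structure (over "slots" named after the donor species),
#' the slot arities it was learned under, the candidate dataset of the second
#' region, and the score used to rate assignments.
#'
#' @slot structure donor [DAGStructure-class] over slot names.
#' @slot slotArities named integer arities the donor model assumes per slot.
#' @slot data2 [DiscreteDataset-class] of the second region.
#' @slot pool candidate species of `data2` eligible for assignment.
#' @slot fixed named character: donor nodes with a fixed region-2 column
#'   (e.g. the collapse class node); never reassigned by the search.
#' @slot scoreKind `"bic"` (default), `"k2"`, or `"transfer"` (donor-
#'   parametrized log-likelihood; requires `donorCPTs`).
#' @slot donorCPTs [CPTSet-class] fit on the donor region (used by the
#'   `"transfer"` score; may be an empty placeholder otherwise).
#' @seealso [EquivalenceProblem()], [functionalEquivalenceSearch()]
#' @export
setClass("EquivalenceProblem",
  representation(structure = "DAGStructure", slotArities = "integer",
                 data2 = "DiscreteDataset", pool = "character",
                 fixed = "character", scoreKind = "character",
                 donorCPTs = "CPTSet"))

setValidity("EquivalenceProblem", function(object) {
  msg <- character()
  if (!all(object@pool %in% colnames(object@data2@records)))
    msg <- c(msg, "pool must be a subset of data2 variables")
  nSlots <- sum(!grepl("\\.lag$", object@structure@nodes)) -
    length(object@fixed)
  if (length(object@pool) < nSlots)
    msg <- c(msg, "candidate pool smaller than the number of slots")
  if (length(object@fixed)) {
    if (!all(names(object@fixed) %in% object@structure@nodes))
      msg <- c(msg, "fixed slots must be structure nodes")
    if (!all(object@fixed %in% colnames(object@data2@records)))
      msg <- c(msg, "fixed columns must exist in data2")
  }
  if (!identical(sort(names(object@slotArities)), sort(object@structure@nodes)))
    msg <- c(msg, "slotArities must cover every slot")
  if (!object@scoreKind %in% c("bic", "k2", "transfer"))
    msg <- c(msg, "scoreKind must be 'bic', 'k2' or 'transfer'")
  if (object@scoreKind == "transfer" &&
      !all(object@structure@nodes %in% names(object@donorCPTs@tables)))
    msg <- c(msg, "transfer scoring needs donor CPTs for every node")
  if (length(msg)) msg else TRUE
})

#' EquivalenceResult: output of the annealing search
#'
#' @slot assignment final slot -> species mapping (the algorithm's raw output).
#' @slot finalScore score of `assignment`.
#' @slot bestAssignment best-ever mapping seen during the run (recommended).
#' @slot bestScore score of `bestAssignment`.
#' @slot trace per-iteration current score (after accept/reject).
#' @slot accepted number of accepted moves.
#' @slot schedule list with `tStart`, `iterations`, `coolingFactor`, `seed`.
#' @export
setClass("EquivalenceResult",
  representation(assignment = "character", finalScore = "numeric",
                 bestAssignment = "character", bestScore = "numeric",
                 trace = "numeric", accepted = "integer", schedule = "list"))

#' DBNModel: two-slice dynamic Bayesian network with one binary latent node
#'
#' Observable nodes carry parents in the previous time slice only; a latent
#' regime node H evolves by `H[t-1] -> H[t]` and (by default) feeds the
#' target node, whose emission table is conditioned on both its lagged
#' observable parents and the current regime.
#'
#' @slot obsNodes observable node names (target included).
#' @slot target name of the predicted node (e.g. cod biomass).
#' @slot interParents named list: lagged observable parents per node.
#' @slot arities named integer arities of the observables.
#' @slot stateLabels state labels per observable.
#' @slot nHidden number of latent states (2 = pre/collapsed).
#' @slot hiddenChildren observables whose emission is conditioned on the
#'   latent state (always includes the target; by default all observables,
#'   since a functional collapse is a community-wide regime).
#' @slot initial initial latent distribution `P(H[1])`.
#' @slot transition `nHidden x nHidden` latent transition matrix (rows = from).
#' @slot hiddenCPTs named list of arrays `q x nHidden x r`:
#'   `P(node | lagged parents, H)` for each hidden child.
#' @slot obsCPTs stochastic `q x r` tables for observables outside
#'   `hiddenChildren`.
#' @slot hiddenLabels labels of the latent states; after alignment state 2 is
#'   "collapsed".
#' @seealso [dbnSkeleton()], [fitEM()], [predictOneStep()], [transferModel()]
#' @export
setClass("DBNModel",
  representation(obsNodes = "character", target = "character",
                 interParents = "list", arities = "integer",
                 stateLabels = "list", nHidden = "integer",
                 hiddenChildren = "character",
                 initial = "numeric", transition = "matrix",
                 hiddenCPTs = "list", obsCPTs = "list",
                 hiddenLabels = "character"))

setValidity("DBNModel", function(object) {
  msg <- character()
  if (!object@target %in% object@obsNodes) msg <- c(msg, "target must be an observable node")
  if (!identical(names(object@interParents), object@obsNodes))
    msg <- c(msg, "interParents must be named after obsNodes")
  if (!object@target %in% object@hiddenChildren)
    msg <- c(msg, "the target must be a hidden child")
  if (!all(object@hiddenChildren %in% object@obsNodes))
    msg <- c(msg, "hiddenChildren must be observable nodes")
  if (length(object@initial) != object@nHidden ||
      abs(sum(object@initial) - 1) > 1e-12)
    msg <- c(msg, "initial must be a distribution over the latent states")
  if (any(abs(rowSums(object@transition) - 1) > 1e-12))
    msg <- c(msg, "transition rows must sum to 1")
  if (!setequal(names(object@hiddenCPTs), object@hiddenChildren))
    msg <- c(msg, "hiddenCPTs must cover exactly the hidden children")
  else for (v in object@hiddenChildren) {
    tc <- object@hiddenCPTs[[v]]
    if (length(dim(tc)) != 3L || dim(tc)[2] != object@nHidden ||
        dim(tc)[3] != object@arities[[v]]) {
      msg <- c(msg, sprintf("hiddenCPTs[['%s']] must be q x nHidden x r", v))
    } else if (any(abs(apply(tc, c(1, 2), sum) - 1) > 1e-10)) {
      msg <- c(msg, sprintf("hiddenCPTs[['%s']] slices must be stochastic", v))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TransitionDataset: consecutive-year state pairs
#'
#' Lagged (slice t-1) and current (slice t) state matrices built from pairs of
#' consecutive survey years only; survey gaps contribute no pair.
#'
#' @slot prev integer matrix of slice t-1 states.
#' @slot cur integer matrix of slice t states.
#' @slot arities named integer arities.
#' @slot stateLabels per-variable state labels.
#' @slot pairYears calendar year of slice t for each pair.
#' @slot newSegment logical; TRUE where a pair starts a fresh consecutive run
#'   (the latent chain restarts from its initial distribution there).
#' @seealso [makeTransitionDataset()]
#' @export
setClass("TransitionDataset",
  representation(prev = "matrix", cur = "matrix", arities = "integer",
                 stateLabels = "list", pairYears = "integer",
                 newSegment = "logical"))

setValidity("TransitionDataset", function(object) {
  msg <- character()
  if (nrow(object@prev) != nrow(object@cur)) msg <- c(msg, "prev/cur row mismatch")
  if (nrow(object@prev) < 1L) msg <- c(msg, "at least one consecutive-year pair required")
  if (!identical(colnames(object@prev), colnames(object@cur)))
    msg <- c(msg, "prev/cur column mismatch")
  if (length(object@newSegment) != nrow(object@prev))
    msg <- c(msg, "one newSegment flag per pair required")
  if (length(msg)) msg else TRUE
})

#' BNClassifier: Bayesian-network classifier over a binary class node
#'
#' @slot structure [DAGStructure-class] over the class node and selected species.
#' @slot cpts Laplace-smoothed [CPTSet-class].
#' @slot className the distinguished class node.
#' @seealso [buildClassifier()], [classify()]
#' @export
setClass("BNClassifier",
  representation(structure = "DAGStructure", cpts = "CPTSet",
                 className = "character"))
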