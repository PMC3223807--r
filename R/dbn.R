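#' Build consecutive-year transition pairs
#'
#' Pairs slice t-1 with slice t for every pair of consecutive calendar
#' years; survey gaps contribute no pair, and each maximal run of
#' consecutive years becomes a segment (the latent chain restarts at segment
#' boundaries).
#'
#' @param dataset a [DiscreteDataset-class].
#' @param years integer calendar year of each record, aligned with the rows.
#' @return a [TransitionDataset-class] with `M_T <= M - 1` pairs.
#' @examples
#' d <- DiscreteDataset(cbind(a = c(1L, 2L, 1L, 2L)))
#' makeTransitionDataset(d, c(2000L, 2001L, 2003L, 2004L))  # 2 pairs
#' @export
makeTransitionDataset <- function(dataset, years) {
  stopIfNot(length(years) == nRecords(dataset),
            "years must align with records")
  years <- as.integer(years)
  stopIfNot(!is.unsorted(years, strictly = TRUE),
            "years must be strictly increasing")
  keep <- which(diff(years) == 1L)
  if (length(keep) < 1L) {
    stop("fewer than 2 consecutive years: no transition pairs", call. = FALSE)
  }
  rec <- stateRecords(dataset)
  prev <- rec[keep, , drop = FALSE]
  cur <- rec[keep + 1L, , drop = FALSE]
  pairYears <- years[keep + 1L]
  newSegment <- c(TRUE, diff(pairYears) != 1L)
  new("TransitionDataset", prev = prev, cur = cur,
      arities = arities(dataset), stateLabels = stateLabels(dataset),
      pairYears = pairYears, newSegment = newSegment)
}

#' Flatten records into a lag + current two-slice dataset
#'
#' Builds a [DiscreteDataset-class] whose first `n` columns are the
#' previous-year states (named `"<var>.lag"`) and whose last `n` columns
#' are the current-year states, one row per consecutive-year pair.  This is
#' the input for scoring two-slice donor structures in the
#' functional-equivalence search.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param years calendar years aligned with the records.
#' @return a [DiscreteDataset-class] with `2 * n` columns.
#' @seealso [EquivalenceProblem()], [makeTransitionDataset()]
#' @export
flattenTransitions <- function(dataset, years) {
  tdata <- makeTransitionDataset(dataset, years)
  prev <- tdata@prev
  colnames(prev) <- paste0(colnames(prev), ".lag")
  rec <- cbind(prev, tdata@cur)
  ar <- c(setNames(unname(tdata@arities), colnames(prev)), tdata@arities)
  labs <- c(setNames(tdata@stateLabels, colnames(prev)), tdata@stateLabels)
  DiscreteDataset(rec, ar, labs)
}

#' @rdname accessors
#' @export
setMethod("nRecords", "TransitionDataset", function(x) nrow(x@prev))
#' @rdname accessors
#' @export
setMethod("variableNames", "TransitionDataset", function(x) colnames(x@cur))
#' @rdname accessors
#' @export
setMethod("arities", "TransitionDataset", function(x) x@arities)

setMethod("show", "TransitionDataset", function(object) {
  cat(sprintf("TransitionDataset: %d pairs, %d variables, %d segment(s)\n",
              nRecords(object), ncol(object@cur), sum(object@newSegment)))
})

#' REVEAL-style greedy inter-slice structure search
#'
#' For each target node at slice t, greedily adds the slice t-1 parent that
#' most improves the family score until no strict improvement remains or the
#' parent cap is hit.  All edges cross slices, so acyclicity of the unrolled
#' graph is automatic and each node's search is independent.
#'
#' @param tdata a [TransitionDataset-class].
#' @param targets slice-t nodes to find parents for (default: all).
#' @param maxParents cap on lagged parents per node (default 3).
#' @param scoreKind `"bic"` (default) or `"k2"`.
#' @param excludeSelf nodes whose own lag is withheld from their candidate
#'   parents.  Used for the node a latent regime variable should explain:
#'   a self-lag parent absorbs the level persistence that distinguishes
#'   the regimes, leaving the hidden node nothing to account for.
#' @return named list: lagged parent names per target.
#' @export
revealSearch <- function(tdata, targets = NULL, maxParents = 3L,
                         scoreKind = c("bic", "k2"),
                         excludeSelf = character(0)) {
  scoreKind <- match.arg(scoreKind)
  vars <- colnames(tdata@cur)
  if (is.null(targets)) targets <- vars
  stopIfNot(all(targets %in% vars), "unknown target node")
  np <- ncol(tdata@prev)
  lapply(setNames(targets, targets), function(v) {
    stacked <- cbind(tdata@prev, tdata@cur[, v, drop = FALSE])
    colnames(stacked) <- c(paste0(vars, ".prev"), ".child")
    ar <- c(unname(tdata@arities[vars]), tdata@arities[[v]])
    cand <- seq_len(np)
    if (v %in% excludeSelf) cand <- cand[vars[cand] != v]
    chosen <- if (maxParents > 0L && length(cand)) {
      .greedyParentsC(stacked, np + 1L, as.integer(cand), as.integer(ar),
                      as.integer(maxParents), scoreKind)
    } else integer(0)
    vars[chosen]
  })
}

#' Create an unparametrized latent-DBN skeleton
#'
#' Fixes the inter-slice structure and hands back a [DBNModel-class] with
#' uniform tables, ready for [fitEM()].  The binary latent regime node H
#' has the autoregressive link `H[t-1] -> H[t]` and feeds the
#' `hiddenChildren`: each such node's emission is
#' `P(node[t] | lagged parents, H[t])`.  By default every observable is a
#' hidden child -- a functional collapse is a community-wide regime, and
#' accumulating the regime evidence across all emissions is what lets the
#' latent state track it rather than residual noise of a single node.
#'
#' @param interParents named list of lagged parents per observable (e.g.
#'   from [revealSearch()]); must include an entry (possibly empty) for each
#'   observable.
#' @param target the predicted node.
#' @param arities named integer arities of the observables.
#' @param stateLabels optional per-variable state labels.
#' @param nHidden number of latent states (default 2, the binary
#'   pre/collapsed framing; more states are a config knob).
#' @param hiddenChildren observables fed by H (default all; must include
#'   the target).
#' @return a [DBNModel-class] with uniform tables.
#' @export
dbnSkeleton <- function(interParents, target, arities, stateLabels = NULL,
                        nHidden = 2L, hiddenChildren = names(interParents)) {
  obs <- names(interParents)
  stopIfNot(target %in% obs, "target must have an interParents entry")
  stopIfNot(all(unlist(interParents) %in% obs), "unknown lagged parent")
  arities <- setNames(as.integer(arities[obs]), obs)
  if (is.null(stateLabels)) {
    stateLabels <- lapply(arities, function(r) paste0("s", seq_len(r)))
  }
  nHidden <- as.integer(nHidden)
  free <- setdiff(obs, hiddenChildren)
  hiddenCPTs <- lapply(setNames(hiddenChildren, hiddenChildren),
                       function(v) {
    q <- prod(arities[interParents[[v]]])
    array(1 / arities[[v]], dim = c(q, nHidden, arities[[v]]))
  })
  obsCPTs <- lapply(setNames(free, free), function(v) {
    q <- prod(arities[interParents[[v]]])
    matrix(1 / arities[[v]], q, arities[[v]])
  })
  new("DBNModel", obsNodes = obs, target = target,
      interParents = interParents, arities = arities,
      stateLabels = stateLabels[obs], nHidden = nHidden,
      hiddenChildren = hiddenChildren,
      initial = rep(1 / nHidden, nHidden),
      transition = matrix(1 / nHidden, nHidden, nHidden),
      hiddenCPTs = hiddenCPTs, obsCPTs = obsCPTs,
      hiddenLabels = if (nHidden == 2L) c("baseline", "collapsed")
                     else paste0("h", seq_len(nHidden)))
}

setMethod("show", "DBNModel", function(object) {
  cat(sprintf(
    "DBNModel: target '%s' (parents: %s) + %d other observables, %d latent states\n",
    object@target,
    if (length(object@interParents[[object@target]]))
      paste(object@interParents[[object@target]], collapse = ", ")
    else "none",
    length(object@obsNodes) - 1L, object@nHidden))
})
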