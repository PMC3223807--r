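#' Greedy K2 structure search
#'
#' Starting from an unconnected graph, each node (visited in `nodeOrder`)
#' greedily acquires the single predecessor parent that most improves its
#' family score, stopping when no strict improvement remains or
#' `maxParents` is reached.  Only predecessors in the order are eligible, so
#' acyclicity is automatic.  Deterministic given its inputs; score ties are
#' broken in favour of the earliest node in the order.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param nodeOrder total order over (a subset of) the dataset's variables;
#'   defaults to the dataset's column order.  For classification place the
#'   class node last, preceded by species in filter-rank order.
#' @param maxParents cap on parents per node (default 3).
#' @param scoreKind `"k2"` (Cooper-Herskovits, default) or `"bic"`.
#' @return a [DAGStructure-class] over `nodeOrder`.
#' @examples
#' d <- DiscreteDataset(cbind(a = rep(1:2, 10), b = rep(1:2, 10)))
#' k2Search(d)  # a -> b: b copies a
#' @export
k2Search <- function(dataset, nodeOrder = NULL, maxParents = 3L,
                     scoreKind = c("k2", "bic")) {
  scoreKind <- match.arg(scoreKind)
  stopIfNot(maxParents >= 0L, "maxParents must be >= 0")
  if (is.null(nodeOrder)) nodeOrder <- variableNames(dataset)
  stopIfNot(!anyDuplicated(nodeOrder), "nodeOrder must not repeat nodes")
  rec <- stateRecords(dataset)
  ar <- arities(dataset)
  idx <- .colIdx(dataset, nodeOrder)
  parents <- setNames(vector("list", length(nodeOrder)), nodeOrder)
  for (i in seq_along(nodeOrder)) {
    cand <- idx[seq_len(i - 1L)]
    chosen <- if (length(cand) && maxParents > 0L) {
      .greedyParentsC(rec, idx[i], cand, ar, as.integer(maxParents), scoreKind)
    } else integer(0)
    parents[[i]] <- variableNames(dataset)[chosen]
  }
  DAGStructure(nodeOrder, parents, nodeOrder)
}
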