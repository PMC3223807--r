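# Exact inference by variable elimination on discrete factors.
#
# A factor is list(vars, values): `values` is a flat vector over the grid of
# states of `vars`, first variable varying fastest (the same linearisation
# the scoring kernel uses).

.fnew <- function(vars, values) list(vars = vars, values = values)

.fgrid <- function(vars, ar) {
  if (!length(vars)) return(matrix(integer(0), 1, 0))
  arrayInd(seq_len(prod(ar[vars])), ar[vars])
}

.fprod <- function(f1, f2, ar) {
  if (!length(f1$vars)) return(.fnew(f2$vars, f1$values * f2$values))
  if (!length(f2$vars)) return(.fnew(f1$vars, f2$values * f1$values))
  vars <- union(f1$vars, f2$vars)
  grid <- .fgrid(vars, ar)
  i1 <- configIndex(grid[, match(f1$vars, vars), drop = FALSE], ar[f1$vars])
  i2 <- configIndex(grid[, match(f2$vars, vars), drop = FALSE], ar[f2$vars])
  .fnew(vars, f1$values[i1] * f2$values[i2])
}

.fmarg <- function(f, var, ar) {
  keep <- setdiff(f$vars, var)
  if (!length(keep)) return(.fnew(character(0), sum(f$values)))
  grid <- .fgrid(f$vars, ar)
  g <- configIndex(grid[, match(keep, f$vars), drop = FALSE], ar[keep])
  .fnew(keep, as.vector(rowsum(f$values, g, reorder = TRUE)))
}

.freduce <- function(f, var, state, ar) {
  if (!var %in% f$vars) return(f)
  keep <- setdiff(f$vars, var)
  grid <- .fgrid(f$vars, ar)
  sel <- grid[, match(var, f$vars)] == state
  .fnew(keep, f$values[sel])
}

#' Exact posterior by variable elimination
#'
#' Computes `P(query | evidence)` exactly by sum-product variable
#' elimination with a min-degree elimination heuristic.  Networks handled
#' here are small and sparse, so exact inference is always feasible.
#'
#' @param dag a [DAGStructure-class].
#' @param cpts a matching [CPTSet-class].
#' @param evidence named integer vector/list of observed states (1-based);
#'   may be empty.  Evidence with probability zero is an error.
#' @param query character vector of query nodes, disjoint from the evidence.
#' @return an array of posterior probabilities over the query nodes (summing
#'   to 1), dimensions named after the query variables.
#' @examples
#' dag <- DAGStructure(c("a", "b"), list(b = "a"))
#' d <- DiscreteDataset(cbind(a = c(1L, 1L, 2L, 2L), b = c(1L, 2L, 2L, 2L)))
#' cp <- fitParameters(d, dag, "laplace")
#' inferPosterior(dag, cp, evidence = c(b = 2L), query = "a")
#' @export
inferPosterior <- function(dag, cpts, evidence = list(), query) {
  ar <- cpts@arities
  evidence <- unlist(evidence)
  stopIfNot(all(names(evidence) %in% dag@nodes), "evidence on unknown node")
  stopIfNot(all(query %in% dag@nodes), "query on unknown node")
  stopIfNot(!any(query %in% names(evidence)),
            "query and evidence must be disjoint")
  for (v in names(evidence)) {
    stopIfNot(evidence[[v]] >= 1L && evidence[[v]] <= ar[[v]],
              sprintf("evidence state out of range for '%s'", v))
  }

  factors <- lapply(dag@nodes, function(v)
    .fnew(c(dag@parents[[v]], v), as.vector(cpts@tables[[v]])))
  for (v in names(evidence)) {
    factors <- lapply(factors, .freduce, var = v, state = evidence[[v]],
                      ar = ar)
  }

  elim <- setdiff(dag@nodes, c(names(evidence), query))
  while (length(elim)) {
    # min-degree: eliminate the variable that co-occurs with fewest others
    deg <- vapply(elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(nb, v))
    }, 0L)
    v <- elim[which.min(deg)]
    elim <- setdiff(elim, v)
    inV <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod <- Reduce(function(a, b) .fprod(a, b, ar), factors[inV])
    factors <- c(factors[!inV], list(.fmarg(prod, v, ar)))
  }

  joint <- Reduce(function(a, b) .fprod(a, b, ar), factors)
  Z <- sum(joint$values)
  if (!is.finite(Z) || Z <= 0) stop("impossible evidence", call. = FALSE)
  # re-order the scope to the requested query order
  grid <- .fgrid(query, ar)
  idx <- configIndex(grid[, match(joint$vars, query), drop = FALSE],
                     ar[joint$vars])
  post <- array(joint$values[idx] / Z, dim = ar[query],
                dimnames = setNames(lapply(ar[query], seq_len), query))
  post
}
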