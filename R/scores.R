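# scoring plumbing: resolve variable names to column indices once per call
.colIdx <- function(dataset, vars) {
  idx <- match(vars, variableNames(dataset))
  if (anyNA(idx)) {
    stop(sprintf("variable(s) not in dataset: %s",
                 paste(vars[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  as.integer(idx)
}

#' Family sufficient statistics
#'
#' Tallies, for every node of `dag`, the counts `F_ijk`: how often node i is
#' in state k while its parents are in (linearised) instantiation j.  Row
#' sums per node give the parent-instantiation marginals `F_ij`; the grand
#' sum per node equals the number of records.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param dag a [DAGStructure-class] whose nodes occur in `dataset`.
#' @return named list of `q_i x r_i` count matrices, one per node, each with
#'   attribute `parents`.
#' @export
collectStats <- function(dataset, dag) {
  rec <- stateRecords(dataset)
  ar <- arities(dataset)
  out <- lapply(setNames(dag@nodes, dag@nodes), function(v) {
    F <- .familyCountsC(rec, .colIdx(dataset, v),
                        .colIdx(dataset, dag@parents[[v]]), ar)
    attr(F, "parents") <- dag@parents[[v]]
    F
  })
  out
}

#' Cooper-Herskovits (K2) family score
#'
#' The log marginal likelihood of one node's family under uniform Dirichlet
#' parameter priors:
#' `sum_j [ lgamma(r_i) - lgamma(F_ij + r_i) + sum_k lgamma(F_ijk + 1) ]`.
#' Decomposable: depends only on this family's counts.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param node child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @return the family score, natural-log space.
#' @examples
#' d <- DiscreteDataset(cbind(a = c(1L, 1L, 2L)), arities = c(a = 2L))
#' k2FamilyScore(d, "a", character(0))  # log(1/12)
#' @export
k2FamilyScore <- function(dataset, node, parents = character(0)) {
  .familyScoreC(stateRecords(dataset), .colIdx(dataset, node),
                .colIdx(dataset, parents), arities(dataset), "k2")
}

#' K2 joint structure-data score
#'
#' `log p(G, D) = log c + sum_i` [k2FamilyScore()] of each family, with `c`
#' the constant structure prior `p(G)`.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param dag a [DAGStructure-class].
#' @param c constant structure prior, `> 0` (default 1, an additive 0).
#' @return a [ScoredNetwork-class].
#' @export
k2NetworkScore <- function(dataset, dag, c = 1) {
  stopIfNot(c > 0, "structure prior c must be positive")
  s <- sum(vapply(dag@nodes, function(v)
    k2FamilyScore(dataset, v, dag@parents[[v]]), 0))
  new("ScoredNetwork", structure = dag, scoreValue = log(c) + s,
      scoreKind = "k2", priorC = c)
}

setMethod("show", "ScoredNetwork", function(object) {
  cat(sprintf("ScoredNetwork (%s): score %.4f over %d nodes, %d edges\n",
              object@scoreKind, object@scoreValue,
              length(object@structure@nodes), nEdges(object@structure)))
})

#' BIC network score
#'
#' Log-likelihood at the maximum-likelihood parameters minus
#' `(Dim_G / 2) * log M`, natural logs, where
#' `Dim_G = sum_i q_i (r_i - 1)`.  Zero-count cells contribute 0 to the
#' likelihood term.  Decomposable over families; overly connected networks
#' are penalised through `Dim_G`.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param dag a [DAGStructure-class].
#' @return the BIC score (higher is better).
#' @export
bicScore <- function(dataset, dag) {
  rec <- stateRecords(dataset)
  ar <- arities(dataset)
  sum(vapply(dag@nodes, function(v)
    .familyScoreC(rec, .colIdx(dataset, v), .colIdx(dataset, dag@parents[[v]]),
                  ar, "bic"), 0))
}

#' Fit conditional probability tables
#'
#' Maximum-likelihood (`theta_ijk = F_ijk / F_ij`; unseen parent rows fall
#' back to uniform) or Laplace add-one (`(F_ijk + 1) / (F_ij + r_i)`, always
#' strictly positive) estimates for a fixed structure.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param dag a [DAGStructure-class].
#' @param estimator `"mle"` or `"laplace"`.
#' @return a [CPTSet-class].
#' @export
fitParameters <- function(dataset, dag, estimator = c("mle", "laplace")) {
  estimator <- match.arg(estimator)
  stats <- collectStats(dataset, dag)
  ar <- arities(dataset)
  tables <- lapply(setNames(dag@nodes, dag@nodes), function(v) {
    F <- stats[[v]]
    r <- ar[[v]]
    th <- if (estimator == "laplace") {
      (F + 1) / (rowSums(F) + r)
    } else {
      Fj <- rowSums(F)
      t0 <- F / ifelse(Fj == 0, 1, Fj)
      t0[Fj == 0, ] <- 1 / r
      t0
    }
    attr(th, "parents") <- dag@parents[[v]]
    attr(th, "parentArities") <- unname(ar[dag@parents[[v]]])
    th
  })
  new("CPTSet", tables = tables, estimator = estimator,
      arities = ar[dag@nodes])
}

#' @rdname accessors
#' @export
setMethod("dimG", "CPTSet", function(x)
  sum(vapply(names(x@tables), function(v)
    nrow(x@tables[[v]]) * (x@arities[[v]] - 1), 0)))

setMethod("show", "CPTSet", function(object) {
  cat(sprintf("CPTSet (%s): %d nodes, Dim_G = %d\n", object@estimator,
              length(object@tables), dimG(object)))
})

#' Log-likelihood of records under a parametrized network
#'
#' `sum_records sum_nodes log theta(state | parent states)`.  Under MLE
#' parameters an unseen event yields `-Inf` honestly; use Laplace tables
#' where finiteness is required.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param dag the [DAGStructure-class] the tables belong to.
#' @param cpts a [CPTSet-class] consistent with `dag`.
#' @return total log-likelihood (natural log).
#' @export
logLikelihood <- function(dataset, dag, cpts) {
  rec <- stateRecords(dataset)
  ar <- arities(dataset)
  ll <- 0
  for (v in dag@nodes) {
    th <- cpts@tables[[v]]
    pa <- dag@parents[[v]]
    j <- configIndex(rec[, pa, drop = FALSE], unname(ar[pa]))
    ll <- ll + sum(log(th[cbind(j, rec[, v])]))
  }
  ll
}
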