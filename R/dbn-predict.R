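#' One-step-ahead prediction with the latent-regime DBN
#'
#' Runs the filtered recursion: the latent predictive
#' `P(H[t] | obs before t)` comes from the transition applied to the
#' previous filtered posterior (the initial distribution at the start of
#' each consecutive-year segment, flagged `fromPrior`); the target's
#' predictive distribution marginalises the latent state and conditions on
#' the lagged observable parents.  Predictions are causal: observations at
#' or after year t never influence the prediction for year t.  Smoothed
#' posteriors and the Viterbi path over the full series are appended for
#' convenience (those are not causal).
#'
#' @param model a fitted [DBNModel-class].
#' @param dataset a [DiscreteDataset-class] covering the model's observables.
#' @param years calendar years aligned with the records.
#' @return a `data.frame` (one row per predicted year): `year`, `observed`,
#'   `predicted` (argmax state, ties to the lower state), `predictedMean`
#'   (expected state, for plot-style traces), `pPredicted` (predictive
#'   probability of latent state 2), `pFiltered`, `pSmoothed` (posterior of
#'   latent state 2), `mapState` and `fromPrior`.
#' @seealso [inferHiddenStates()], [transferModel()]
#' @export
predictOneStep <- function(model, dataset, years) {
  tdata <- makeTransitionDataset(subsetVariables(dataset, model@obsNodes),
                                 years)
  E <- .emissionMatrix(model, tdata)
  fb <- .forwardBackward(model@initial, model@transition, E, tdata@newSegment)
  stopIfNot(is.finite(fb$ll), "observations impossible under the model")
  tp <- model@interParents[[model@target]]
  j <- configIndex(tdata@prev[, tp, drop = FALSE], unname(model@arities[tp]))
  y <- tdata@cur[, model@target]
  rT <- model@arities[[model@target]]
  tCPT <- model@hiddenCPTs[[model@target]]
  P <- nRecords(tdata)
  pred <- integer(P)
  predMean <- numeric(P)
  for (i in seq_len(P)) {
    py <- numeric(rT)
    for (h in seq_len(model@nHidden)) {
      py <- py + fb$predicted[i, h] * tCPT[j[i], h, ]
    }
    pred[i] <- which.max(py)  # ties resolve to the lower state
    predMean[i] <- sum(seq_len(rT) * py)
  }
  path <- .viterbi(model@initial, model@transition, E, tdata@newSegment)
  data.frame(year = tdata@pairYears, observed = y, predicted = pred,
             predictedMean = predMean,
             pPredicted = fb$predicted[, model@nHidden],
             pFiltered = fb$filtered[, model@nHidden],
             pSmoothed = fb$smoothed[, model@nHidden],
             mapState = path, fromPrior = tdata@newSegment)
}

#' Smoothed latent-state posteriors and MAP path
#'
#' Forward-backward smoothing `P(H[t] | all observations)` plus the
#' max-product (Viterbi) most probable latent trajectory.
#'
#' @param model a fitted [DBNModel-class].
#' @param dataset a [DiscreteDataset-class] covering the model's observables.
#' @param years calendar years aligned with the records.
#' @return a `data.frame` with `year`, `pSmoothed` (posterior probability of
#'   latent state 2, the "collapsed" label after alignment) and `mapState`.
#' @export
inferHiddenStates <- function(model, dataset, years) {
  tdata <- makeTransitionDataset(subsetVariables(dataset, model@obsNodes),
                                 years)
  E <- .emissionMatrix(model, tdata)
  fb <- .forwardBackward(model@initial, model@transition, E, tdata@newSegment)
  stopIfNot(is.finite(fb$ll), "observations impossible under the model")
  path <- .viterbi(model@initial, model@transition, E, tdata@newSegment)
  data.frame(year = tdata@pairYears, pSmoothed = fb$smoothed[, model@nHidden],
             mapState = path)
}

#' Fix the latent label switching
#'
#' EM labels are arbitrary; this aligns them so that state 2 is the
#' "collapsed-like" regime: if the majority MAP state over the
#' post-collapse years is state 1, all latent dimensions are flipped.
#' Binary latent node only.
#'
#' @param model a fitted [DBNModel-class] with `nHidden = 2`.
#' @param dataset,years the series the model was fitted on.
#' @param collapseYear the known (or assumed) collapse year.
#' @return the model, relabelled if necessary.
#' @export
alignHiddenLabels <- function(model, dataset, years, collapseYear) {
  stopIfNot(model@nHidden == 2L, "label alignment is defined for 2 states")
  hs <- inferHiddenStates(model, dataset, years)
  post <- hs$mapState[hs$year >= collapseYear]
  if (length(post) == 0L) return(model)
  if (mean(post == 2L) >= 0.5) return(model)
  flip <- c(2L, 1L)
  model@initial <- model@initial[flip]
  model@transition <- model@transition[flip, flip, drop = FALSE]
  model@hiddenCPTs <- lapply(model@hiddenCPTs, function(tc)
    tc[, flip, , drop = FALSE])
  model
}

#' Transfer a donor model onto mapped species of another region
#'
#' Relabels the donor structure *and* the donor parameters onto the mapped
#' target-region species — the tables learned in the donor region are
#' carried over verbatim (no re-fitting; set `refit = TRUE` to re-estimate
#' them on the target region instead) — then runs the one-step-ahead
#' prediction and latent-state inference on the target data.
#'
#' @param donor a fitted [DBNModel-class] (donor region).
#' @param mapping an [EquivalenceResult-class] (its best-ever assignment is
#'   used) or a named character vector slot -> target species covering every
#'   observable of `donor`.
#' @param targetData [DiscreteDataset-class] of the target region;
#'   arity-compatible columns required.
#' @param years calendar years of the target records.
#' @param refit re-estimate all tables on the target region by EM
#'   ([fitEM()] with defaults) instead of carrying them over.
#' @return a `data.frame` as from [predictOneStep()], with the relabelled
#'   model attached as attribute `"model"`.
#' @export
transferModel <- function(donor, mapping, targetData, years, refit = FALSE) {
  if (is(mapping, "EquivalenceResult")) mapping <- bestAssignment(mapping)
  missing <- setdiff(donor@obsNodes, names(mapping))
  if (length(missing)) {
    stop(sprintf("unmapped slot(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  mapping <- mapping[donor@obsNodes]
  stopIfNot(!anyDuplicated(mapping), "mapping must be injective")
  stopIfNot(all(mapping %in% variableNames(targetData)),
            "mapped species missing from the target data")
  arT <- arities(targetData)[unname(mapping)]
  if (any(unname(arT) != unname(donor@arities))) {
    stop("arity mismatch between donor slots and mapped target columns",
         call. = FALSE)
  }
  ren <- function(v) unname(mapping[v])
  model <- donor
  model@obsNodes <- ren(donor@obsNodes)
  model@target <- ren(donor@target)
  model@hiddenChildren <- ren(donor@hiddenChildren)
  model@interParents <- setNames(lapply(donor@interParents, ren),
                                 model@obsNodes)
  model@arities <- setNames(unname(donor@arities), model@obsNodes)
  model@stateLabels <- stateLabels(targetData)[model@obsNodes]
  names(model@obsCPTs) <- ren(names(donor@obsCPTs))
  names(model@hiddenCPTs) <- ren(names(donor@hiddenCPTs))
  if (refit) {
    model <- fitEM(model, makeTransitionDataset(
      subsetVariables(targetData, model@obsNodes), years))$model
  }
  out <- predictOneStep(model, targetData, years)
  attr(out, "model") <- model
  out
}

#' Write a prediction series as CSV
#'
#' Columns `year,observed,predicted,p_hidden_state1,map_state` (plus the
#' remaining columns of [predictOneStep()]'s output).
#'
#' @param series a `data.frame` from [predictOneStep()] or [transferModel()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePredictionSeries <- function(series, file) {
  df <- data.frame(year = series$year, observed = series$observed,
                   predicted = series$predicted,
                   p_hidden_state1 = series$pSmoothed,
                   map_state = series$mapState)
  extra <- setdiff(names(series),
                   c("year", "observed", "predicted", "pSmoothed", "mapState"))
  df <- cbind(df, series[extra])
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' DBN model JSON round trip
#'
#' Serialises structure, tables and the discretization vocabulary; arrays
#' are stored flat with their dimensions.
#'
#' @param model a [DBNModel-class].
#' @param file path of the JSON file.
#' @return `writeDBNModel()` returns `file` invisibly; `readDBNModel()`
#'   returns the restored [DBNModel-class].
#' @export
writeDBNModel <- function(model, file) {
  out <- list(obsNodes = model@obsNodes, target = model@target,
              interParents = model@interParents,
              arities = as.list(model@arities),
              stateLabels = model@stateLabels,
              nHidden = model@nHidden,
              hiddenChildren = model@hiddenChildren,
              initial = model@initial,
              transition = as.vector(model@transition),
              hiddenCPTs = lapply(model@hiddenCPTs, function(a)
                list(dim = dim(a), values = as.vector(a))),
              obsCPTs = lapply(model@obsCPTs, function(m)
                list(dim = dim(m), values = as.vector(m))),
              hiddenLabels = model@hiddenLabels)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeDBNModel
#' @export
readDBNModel <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  ip <- lapply(x$interParents, function(p) as.character(unlist(p)))
  nH <- as.integer(x$nHidden)
  new("DBNModel", obsNodes = x$obsNodes, target = x$target,
      interParents = setNames(ip, x$obsNodes),
      arities = setNames(as.integer(unlist(x$arities)), names(x$arities)),
      stateLabels = lapply(x$stateLabels, as.character),
      nHidden = nH, hiddenChildren = as.character(x$hiddenChildren),
      initial = as.numeric(x$initial),
      transition = matrix(as.numeric(x$transition), nH, nH),
      hiddenCPTs = lapply(x$hiddenCPTs, function(a)
        array(as.numeric(a$values), dim = as.integer(a$dim))),
      obsCPTs = lapply(x$obsCPTs, function(m)
        matrix(as.numeric(m$values), m$dim[1], m$dim[2])),
      hiddenLabels = as.character(x$hiddenLabels))
}
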