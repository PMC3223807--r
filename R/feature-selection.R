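#' Bootstrap filter feature selection
#'
#' Scores each species independently by the Cooper-Herskovits likelihood of
#' the one-edge family linking it with the binary collapse class, averaged
#' over bootstrap resamples.  By default the class is the parent
#' (`class -> species`); the reverse orientation is available since the two
#' are not generally symmetric when arities differ.  `deltaScore` reports
#' the same mean minus the parentless family score of the species on the
#' same resamples, so positive values flag class-informative species.
#'
#' @param labeled a [ClassLabeledDataset-class].
#' @param nBoot number of bootstrap resamples (paper-scale default 1000).
#' @param seed base seed; resample b uses `seed + b - 1`.
#' @param orientation `"class_parent"` (default) or `"species_parent"`.
#' @return a `data.frame` with columns `species`, `meanScore`, `deltaScore`
#'   and `rank`, sorted by decreasing `meanScore`; attributes `method`,
#'   `nBoot`, `seed`.
#' @seealso [wrapperSelect()]
#' @export
filterSelect <- function(labeled, nBoot = 1000L, seed = 1L,
                         orientation = c("class_parent", "species_parent")) {
  orientation <- match.arg(orientation)
  stopIfNot(nBoot >= 1L, "nBoot must be >= 1")
  full <- withClassVariable(labeled)
  cls <- labeled@className
  species <- variableNames(labeled@base)
  score <- matrix(0, nBoot, length(species), dimnames = list(NULL, species))
  base <- score
  for (b in seq_len(nBoot)) {
    ds <- bootstrapResample(full, seed = seed + b - 1L)
    for (s in species) {
      if (orientation == "class_parent") {
        score[b, s] <- k2FamilyScore(ds, s, cls)
        base[b, s] <- k2FamilyScore(ds, s, character(0))
      } else {
        score[b, s] <- k2FamilyScore(ds, cls, s)
        base[b, s] <- k2FamilyScore(ds, cls, character(0))
      }
    }
  }
  ms <- colMeans(score)
  out <- data.frame(species = species, meanScore = unname(ms),
                    deltaScore = unname(ms - colMeans(base)))
  out <- out[order(-out$meanScore), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "method") <- paste0("filter/", orientation)
  attr(out, "nBoot") <- nBoot
  attr(out, "seed") <- seed
  out
}

#' Bootstrap wrapper feature selection
#'
#' On each bootstrap resample a Bayesian-network classifier structure is
#' learned by greedy K2 search with the class node first in the order
#' (class-as-root, as in a selective naive-Bayes classifier) and species by
#' filter rank; a species "hits" when any learned edge links it with the
#' class node, in either direction.  The confidence of a species is the
#' proportion of resamples in which it hits.  A trailing class node would
#' cap the number of linkable species at `maxParents`; the class-as-root
#' order leaves every species free to link, which is what the confidence is
#' meant to measure.
#'
#' @param labeled a [ClassLabeledDataset-class].
#' @param nBoot number of bootstrap resamples (paper-scale default 1000).
#' @param seed base seed; resample b uses `seed + b - 1`.
#' @param maxParents parent cap passed to [k2Search()].
#' @param nodeOrder optional species order for the search; defaults to the
#'   filter-selection ranking computed on the full (unresampled) data.
#' @return a `data.frame` with columns `species`, `confidence` and `rank`,
#'   sorted by decreasing confidence (ties by the search order); attributes
#'   `method`, `nBoot`, `seed`.
#' @export
wrapperSelect <- function(labeled, nBoot = 1000L, seed = 1L, maxParents = 3L,
                          nodeOrder = NULL) {
  stopIfNot(nBoot >= 1L, "nBoot must be >= 1")
  full <- withClassVariable(labeled)
  cls <- labeled@className
  if (is.null(nodeOrder)) {
    nodeOrder <- filterSelect(labeled, nBoot = 1L, seed = seed)$species
  }
  stopIfNot(setequal(nodeOrder, variableNames(labeled@base)),
            "nodeOrder must cover exactly the species")
  hits <- setNames(integer(length(nodeOrder)), nodeOrder)
  for (b in seq_len(nBoot)) {
    ds <- bootstrapResample(full, seed = seed + b - 1L)
    dag <- k2Search(ds, nodeOrder = c(cls, nodeOrder),
                    maxParents = maxParents, scoreKind = "k2")
    e <- edgeList(dag)
    linked <- unique(c(e[e[, "parent"] == cls, "child"],
                       e[e[, "child"] == cls, "parent"]))
    hits[linked] <- hits[linked] + 1L
  }
  out <- data.frame(species = nodeOrder, confidence = unname(hits) / nBoot)
  out <- out[order(-out$confidence), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "method") <- "wrapper"
  attr(out, "nBoot") <- nBoot
  attr(out, "seed") <- seed
  out
}

#' Build a Bayesian-network classifier
#'
#' Restricts the data to the class plus the selected species, learns a
#' structure by greedy K2 search (class first in the order, so the class
#' can be a root feeding any informative species) and fits
#' Laplace-smoothed tables so the classifier never assigns probability zero.
#' An empty selection yields a prior-only classifier, with a warning.
#'
#' @param labeled a [ClassLabeledDataset-class].
#' @param selectedSpecies character vector of species to include.
#' @param maxParents parent cap passed to [k2Search()].
#' @return a [BNClassifier-class].
#' @export
buildClassifier <- function(labeled, selectedSpecies, maxParents = 3L) {
  stopIfNot(all(selectedSpecies %in% variableNames(labeled@base)),
            "selection must be a subset of the species")
  full <- withClassVariable(labeled)
  cls <- labeled@className
  if (length(selectedSpecies) == 0L) {
    warning("empty selection: classifier reduces to the class prior")
  }
  ds <- subsetVariables(full, c(cls, selectedSpecies))
  dag <- k2Search(ds, nodeOrder = c(cls, selectedSpecies),
                  maxParents = maxParents, scoreKind = "k2")
  new("BNClassifier", structure = dag,
      cpts = fitParameters(ds, dag, "laplace"), className = cls)
}

setMethod("show", "BNClassifier", function(object) {
  cat(sprintf("BNClassifier: class '%s' + %d species, %d edges\n",
              object@className, length(object@structure@nodes) - 1L,
              nEdges(object@structure)))
})

#' Class posterior for a (partial) observation
#'
#' @param classifier a [BNClassifier-class].
#' @param observation named integer states over any subset of the
#'   classifier's species; empty returns the class prior.
#' @return numeric posterior over the class states (sums to 1), named
#'   `pre`/`post`.
#' @export
classify <- function(classifier, observation = list()) {
  post <- inferPosterior(classifier@structure, classifier@cpts,
                         evidence = observation,
                         query = classifier@className)
  setNames(as.vector(post), c("pre", "post"))
}
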