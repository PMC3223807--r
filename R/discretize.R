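#' Construct a DiscreteDataset
#'
#' @param records integer matrix of state indices in `1..r_i`, one row per
#'   observation, columns named after the variables.
#' @param arities named integer state counts; defaults to the per-column
#'   maxima of `records`, floored at 2.
#' @param stateLabels named list of ordered state labels; defaults to
#'   `"s1".."sr"` per variable.
#' @return a [DiscreteDataset-class].
#' @export
DiscreteDataset <- function(records, arities = NULL, stateLabels = NULL) {
  records <- as.matrix(records)
  storage.mode(records) <- "integer"
  if (is.null(arities)) {
    arities <- pmax(apply(records, 2, max), 2L)
  }
  arities <- setNames(as.integer(arities), colnames(records))
  if (is.null(stateLabels)) {
    stateLabels <- lapply(arities, function(r) paste0("s", seq_len(r)))
  }
  names(stateLabels) <- colnames(records)
  new("DiscreteDataset", records = records, arities = arities,
      stateLabels = stateLabels)
}

#' @rdname accessors
#' @export
setMethod("variableNames", "DiscreteDataset", function(x) colnames(x@records))
#' @rdname accessors
#' @export
setMethod("nRecords", "DiscreteDataset", function(x) nrow(x@records))
#' @rdname accessors
#' @export
setMethod("arities", "DiscreteDataset", function(x) x@arities)
#' @rdname accessors
#' @export
setMethod("stateRecords", "DiscreteDataset", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("stateLabels", "DiscreteDataset", function(x) x@stateLabels)

setMethod("show", "DiscreteDataset", function(object) {
  cat(sprintf("DiscreteDataset: %d records x %d variables (arities %s)\n",
              nRecords(object), length(arities(object)),
              paste(range(arities(object)), collapse = "-")))
})

#' Restrict a DiscreteDataset to a subset of variables
#' @param x a [DiscreteDataset-class].
#' @param vars variable names to keep (order respected).
#' @return a [DiscreteDataset-class] over `vars`.
#' @export
subsetVariables <- function(x, vars) {
  stopIfNot(all(vars %in% variableNames(x)), "unknown variable requested")
  DiscreteDataset(x@records[, vars, drop = FALSE], x@arities[vars],
                  x@stateLabels[vars])
}

#' Discretize biomass into ordinal states
#'
#' Bins each species independently into `nBins` ordinal states, either by
#' empirical quantiles (equal-frequency; the default, robust to the heavy
#' right skew of survey biomass) or by equal-width intervals.  Bin edges are
#' recorded as the state labels, so the discretization vocabulary travels
#' with the dataset.  Larger biomass never maps to a lower state.  Duplicate
#' quantile edges reduce the arity of that species; a species whose arity
#' would fall below 2 (e.g. constant biomass) is an error unless
#' `dropConstant = TRUE`, in which case it is dropped with a warning.
#'
#' @param table a [BiomassTable-class].
#' @param nBins target number of states per species (`>= 2`); default 3
#'   ("low/medium/high").
#' @param method `"quantile"` or `"equal_width"`.
#' @param transform `"none"` or `"log"` (`log1p`, applied before binning).
#'   Quantile bins are invariant to monotone transforms, so this matters
#'   only for `equal_width`: survey biomass spans orders of magnitude, and
#'   equal-width bins on the log scale give persistent low/high regimes
#'   their own states instead of forcing equal bin occupancy.
#' @param dropConstant drop zero-information species instead of erroring.
#' @return a [DiscreteDataset-class]; record order follows the table's years.
#' @examples
#' bt <- BiomassTable(cbind(a = 1:6, b = c(0, 1, 1, 2, 8, 10)), 2000:2005,
#'                    c("a", "b"))
#' stateRecords(discretizeBiomass(bt, nBins = 3))
#' @export
discretizeBiomass <- function(table, nBins = 3L,
                              method = c("quantile", "equal_width"),
                              transform = c("none", "log"),
                              dropConstant = FALSE) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  stopIfNot(nBins >= 2L, "nBins must be >= 2")
  vals <- biomassValues(table)  # species x years
  if (transform == "log") vals <- log1p(vals)
  recs <- list()
  labs <- list()
  for (sp in rownames(vals)) {
    x <- vals[sp, ]
    if (diff(range(x)) == 0) {
      if (dropConstant) {
        warning(sprintf("dropping constant variable '%s'", sp))
        next
      }
      stop(sprintf("constant variable '%s' carries no information", sp),
           call. = FALSE)
    }
    edges <- if (method == "quantile") {
      unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                      names = FALSE, type = 7))
    } else {
      seq(min(x), max(x), length.out = nBins + 1)
    }
    if (length(edges) < 3L) {
      if (dropConstant) {
        warning(sprintf("dropping near-constant variable '%s'", sp))
        next
      }
      stop(sprintf("variable '%s' cannot support 2 states", sp), call. = FALSE)
    }
    st <- cut(x, breaks = edges, labels = FALSE, include.lowest = TRUE)
    recs[[sp]] <- as.integer(st)
    labs[[sp]] <- sprintf("[%.6g,%.6g]", edges[-length(edges)], edges[-1])
  }
  stopIfNot(length(recs) > 0L, "no usable variables after discretization")
  DiscreteDataset(do.call(cbind, recs), vapply(labs, length, 1L), labs)
}

#' Attach the binary collapse class to a dataset
#'
#' Labels each record pre (1) or post (2) functional collapse from its
#' calendar year: the collapse year itself and all later years are post.  A
#' collapse year outside the observed span triggers a warning (degenerate
#' labelling); an empty class is an error.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param years integer calendar year of each record.
#' @param collapseYear the assumed year of the step change (e.g. 1988 for
#'   Georges Bank, 1992 for the East Scotian Shelf).
#' @param className name for the class variable.
#' @return a [ClassLabeledDataset-class].
#' @export
labelCollapse <- function(dataset, years, collapseYear,
                          className = "collapse") {
  stopIfNot(length(years) == nRecords(dataset),
            "years must align with records")
  years <- as.integer(years)
  collapseYear <- as.integer(collapseYear)
  if (collapseYear <= min(years) || collapseYear > max(years)) {
    warning("collapse year outside the observed span: one-class labelling")
  }
  cls <- ifelse(years >= collapseYear, 2L, 1L)
  if (length(unique(cls)) < 2L) {
    stop("empty class: every record falls on one side of the collapse year",
         call. = FALSE)
  }
  new("ClassLabeledDataset", base = dataset, className = className,
      classValues = cls, years = years, collapseYear = collapseYear)
}

#' @rdname accessors
#' @export
setMethod("variableNames", "ClassLabeledDataset",
          function(x) variableNames(x@base))
#' @rdname accessors
#' @export
setMethod("nRecords", "ClassLabeledDataset", function(x) nRecords(x@base))
#' @rdname accessors
#' @export
setMethod("sampleYears", "ClassLabeledDataset", function(x) x@years)

setMethod("show", "ClassLabeledDataset", function(object) {
  cat(sprintf(
    "ClassLabeledDataset '%s' (collapse %d): %d pre + %d post records, %d species\n",
    object@className, object@collapseYear, sum(object@classValues == 1L),
    sum(object@classValues == 2L), length(variableNames(object))))
})

#' Merge the class variable into the record matrix
#'
#' Returns a plain [DiscreteDataset-class] whose last column is the binary
#' class, the form consumed by scoring and structure search.
#'
#' @param labeled a [ClassLabeledDataset-class].
#' @return a [DiscreteDataset-class] with the class as final variable.
#' @export
withClassVariable <- function(labeled) {
  rec <- cbind(labeled@base@records, labeled@classValues)
  colnames(rec) <- c(variableNames(labeled@base), labeled@className)
  ar <- c(labeled@base@arities, setNames(2L, labeled@className))
  labs <- c(labeled@base@stateLabels,
            setNames(list(c("pre", "post")), labeled@className))
  DiscreteDataset(rec, ar, labs)
}

#' Bootstrap-resample the records of a dataset
#'
#' Draws `nRecords(dataset)` rows with replacement; arities and state labels
#' (the discretization vocabulary) are unchanged, so scores across resamples
#' stay comparable.  Bit-reproducible given `seed`.
#'
#' @param dataset a [DiscreteDataset-class].
#' @param seed integer seed, or `NULL` to draw from the ambient RNG stream.
#' @return a [DiscreteDataset-class] of resampled records.
#' @export
bootstrapResample <- function(dataset, seed = NULL) {
  M <- nRecords(dataset)
  idx <- withSeed(seed, sample.int(M, M, replace = TRUE))
  DiscreteDataset(dataset@records[idx, , drop = FALSE], dataset@arities,
                  dataset@stateLabels)
}
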