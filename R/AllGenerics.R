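#' @include AllClasses.R
NULL

#' Accessors for funcEquiv classes
#'
#' Small accessor generics: `regionId()` and `sampleYears()` for
#' [BiomassTable-class]; `variableNames()`, `nRecords()`, `arities()`,
#' `stateRecords()` and `stateLabels()` for [DiscreteDataset-class] (and, via
#' its base dataset, [ClassLabeledDataset-class]); `parentSets()` and
#' `nodeOrder()` for [DAGStructure-class]; `dimG()` for the parameter
#' dimension of a [CPTSet-class]; `assignment()` and `bestAssignment()` for
#' [EquivalenceResult-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot content; `dimG()` returns
#'   `sum_i q_i (r_i - 1)`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))
#' @rdname accessors
#' @export
setGeneric("sampleYears", function(x) standardGeneric("sampleYears"))
#' @rdname accessors
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))
#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @rdname accessors
#' @export
setGeneric("arities", function(x) standardGeneric("arities"))
#' @rdname accessors
#' @export
setGeneric("stateRecords", function(x) standardGeneric("stateRecords"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("parentSets", function(x) standardGeneric("parentSets"))
#' @rdname accessors
#' @export
setGeneric("nodeOrder", function(x) standardGeneric("nodeOrder"))
#' @rdname accessors
#' @export
setGeneric("dimG", function(x) standardGeneric("dimG"))
#' @rdname accessors
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))
#' @rdname accessors
#' @export
setGeneric("bestAssignment", function(x) standardGeneric("bestAssignment"))
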