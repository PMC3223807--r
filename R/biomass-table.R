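#' Construct a BiomassTable
#'
#' @param values numeric matrix of non-negative biomass, years in rows and
#'   species in columns (the orientation of the survey CSVs); stored
#'   internally species-by-years.
#' @param years integer calendar years, strictly increasing (gaps allowed).
#' @param species character species names, unique.
#' @param regionId short region label (e.g. `"GB"`).
#' @return a [BiomassTable-class].
#' @examples
#' bt <- BiomassTable(matrix(1:6, 3, 2), 2000:2002, c("cod", "herring"), "demo")
#' sampleYears(bt)
#' @export
BiomassTable <- function(values, years, species, regionId = "region") {
  values <- as.matrix(values)
  stopIfNot(nrow(values) == length(years) && ncol(values) == length(species),
            "matrix dimensions must match years x species")
  m <- t(values)
  dimnames(m) <- list(species, as.character(years))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(biomass = m),
    colData = S4Vectors::DataFrame(year = as.integer(years)),
    metadata = list(regionId = regionId))
  new("BiomassTable", se)
}

#' Read a biomass table from CSV
#'
#' Expects a `year` column first, then one numeric column per species.  Rows
#' are re-sorted by year; duplicate years, non-numeric cells and negative
#' biomass are rejected (negative values are reported with their row and
#' column).
#'
#' @param source path to (or connection of) the CSV file; UTF-8, `.` decimal.
#' @param regionId region label to attach.
#' @return a [BiomassTable-class].
#' @export
readBiomassTable <- function(source, regionId = "region") {
  df <- read.csv(source, check.names = FALSE)
  stopIfNot(ncol(df) >= 2L && identical(tolower(names(df)[1]), "year"),
            "CSV must have a 'year' column followed by species columns")
  years <- df[[1]]
  stopIfNot(!anyNA(suppressWarnings(as.integer(years))), "non-integer year")
  years <- as.integer(years)
  if (anyDuplicated(years)) stop("duplicate years in input", call. = FALSE)
  vals <- df[-1]
  for (j in seq_along(vals)) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(x)) stop(sprintf("non-numeric biomass in column '%s'", names(vals)[j]),
                       call. = FALSE)
    neg <- which(x < 0)
    if (length(neg)) stop(sprintf("negative biomass at row %d, column '%s'",
                                  neg[1], names(vals)[j]), call. = FALSE)
    vals[[j]] <- x
  }
  ord <- order(years)
  BiomassTable(as.matrix(vals)[ord, , drop = FALSE], years[ord],
               names(vals), regionId)
}

#' Write a BiomassTable to CSV (year column first)
#' @param x a [BiomassTable-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeBiomassTable <- function(x, file) {
  df <- data.frame(year = sampleYears(x), t(biomassValues(x)),
                   check.names = FALSE)
  names(df)[-1] <- rownames(x)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname accessors
#' @export
setMethod("regionId", "BiomassTable", function(x) S4Vectors::metadata(x)$regionId)

#' @rdname accessors
#' @export
setMethod("sampleYears", "BiomassTable",
          function(x) as.integer(SummarizedExperiment::colData(x)$year))

#' Species-by-year biomass matrix of a BiomassTable
#' @param x a [BiomassTable-class].
#' @return numeric matrix, species in rows, years in columns.
#' @export
biomassValues <- function(x) SummarizedExperiment::assay(x, "biomass")

setMethod("show", "BiomassTable", function(object) {
  cat(sprintf("BiomassTable '%s': %d species x %d years (%d-%d)\n",
              regionId(object), nrow(object), ncol(object),
              min(sampleYears(object)), max(sampleYears(object))))
})
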