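#' Person identifiers of a study
#'
#' @param x a [DailyStudy-class].
#' @return Character vector of person ids.
#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))

#' @rdname personIds
setMethod("personIds", "DailyStudy", function(x) names(x@persons))

#' Number of persons in a study
#'
#' @param x a [DailyStudy-class].
#' @return Integer count.
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))

#' @rdname nPersons
setMethod("nPersons", "DailyStudy", function(x) length(x@persons))

#' Extract one person's series from a study
#'
#' @param x a [DailyStudy-class].
#' @param id person identifier.
#' @return The [PersonSeries-class] for `id`.
#' @export
setGeneric("getPerson", function(x, id) standardGeneric("getPerson"))

#' @rdname getPerson
setMethod("getPerson", "DailyStudy", function(x, id) {
  if (!id %in% names(x@persons))
    stop("unknown person id: ", id)
  x@persons[[id]]
})

#' Day indices of a person series
#'
#' @param x a [PersonSeries-class].
#' @return Integer vector of day indices.
#' @export
setGeneric("seriesDays", function(x) standardGeneric("seriesDays"))

#' @rdname seriesDays
setMethod("seriesDays", "PersonSeries", function(x) x@day)

#' Value matrix of a person series
#'
#' @param x a [PersonSeries-class].
#' @return Numeric day-by-variable matrix with `NA` for missing cells.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesValues
setMethod("seriesValues", "PersonSeries", function(x) x@values)

#' Observation mask of a person series
#'
#' @param x a [PersonSeries-class].
#' @return Logical day-by-variable matrix.
#' @export
setGeneric("seriesObserved", function(x) standardGeneric("seriesObserved"))

#' @rdname seriesObserved
setMethod("seriesObserved", "PersonSeries", function(x) x@observed)

#' Phase indicator of a person series
#'
#' @param x a [PersonSeries-class].
#' @return Integer 0/1 vector (with NA on missed days), or `NULL`.
#' @export
setGeneric("seriesPhase", function(x) standardGeneric("seriesPhase"))

#' @rdname seriesPhase
setMethod("seriesPhase", "PersonSeries", function(x) x@phase)

#' Scale metadata of a person series
#'
#' @param x a [PersonSeries-class].
#' @return Named list of [ScaleSpec-class] objects.
#' @export
setGeneric("seriesScales", function(x) standardGeneric("seriesScales"))

#' @rdname seriesScales
setMethod("seriesScales", "PersonSeries", function(x) x@scales)

#' Variable names of a person series
#'
#' @param x a [PersonSeries-class].
#' @return Character vector.
#' @export
setGeneric("seriesVariables", function(x) standardGeneric("seriesVariables"))

#' @rdname seriesVariables
setMethod("seriesVariables", "PersonSeries", function(x) colnames(x@values))

#' Fit indices of a fitted model
#'
#' @param x a [USEMModel-class].
#' @return The [FitIndices-class] of the fit.
#' @export
setGeneric("modelFit", function(x) standardGeneric("modelFit"))

#' @rdname modelFit
setMethod("modelFit", "USEMModel", function(x) x@fit)

#' Parameter table of a fitted model
#'
#' @param x a [USEMModel-class].
#' @return data.frame of free structural parameters with est, se, z, p.
#' @export
setGeneric("modelEstimates", function(x) standardGeneric("modelEstimates"))

#' @rdname modelEstimates
setMethod("modelEstimates", "USEMModel", function(x) x@estimates)

## ---- show methods -----------------------------------------------------

setMethod("show", "ScaleSpec", function(object) {
  cat(sprintf("ScaleSpec '%s': [%g, %g]%s%s\n", object@name, object@min,
              object@max, if (object@integerValued) " integer" else "",
              if (length(object@items))
                paste0(", items: ", paste(object@items, collapse = ", "))
              else ""))
})

setMethod("show", "PersonSeries", function(object) {
  cat(sprintf("PersonSeries '%s': %d days, %d variables (%s)\n",
              object@personId, length(object@day), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
  obs <- round(100 * mean(object@observed), 1)
  cat(sprintf("  observed cells: %s%%; phase recorded: %s\n", obs,
              if (is.null(object@phase)) "no" else "yes"))
})

setMethod("show", "DailyStudy", function(object) {
  cat(sprintf("DailyStudy: %d persons, nominal length %d days\n",
              length(object@persons), object@studyLength))
  if (length(object@persons))
    cat("  persons:", paste(names(object@persons), collapse = ", "), "\n")
})

setMethod("show", "FitIndices", function(object) {
  cat(sprintf(
    "chi2(%d) = %.3f, p = %.3f | RMSEA = %.3f, SRMR = %.3f, CFI = %.3f, NNFI = %.3f (%d/4 excellent)\n",
    object@df, object@chi2, object@pChi2, object@rmsea, object@srmr,
    object@cfi, object@nnfi, object@nExcellent))
})

setMethod("show", "USEMModel", function(object) {
  cat(sprintf("USEMModel: p = %d, N = %d, %d free structural parameters%s\n",
              object@spec@p, object@N, nrow(object@estimates),
              if (object@heywood) " [Heywood: bounded residual variance]"
              else ""))
  cat("  fit: ")
  show(object@fit)
})

setMethod("show", "SearchTrace", function(object) {
  cat(sprintf("SearchTrace: %d accepted steps, stopped: %s\n",
              nrow(object@steps), object@stopReason))
})

setMethod("show", "ResidRegResult", function(object) {
  cat(sprintf("ResidRegResult '%s' (n = %d, AR(1) phi = %.3f on %d pairs; reference milieu: %s)\n",
              object@personId, object@nUsed, object@arCoef, object@arN,
              object@referenceLevel))
  print(object@coefficients, row.names = FALSE, digits = 3)
})

setMethod("show", "SimpleSlopes", function(object) {
  cat(sprintf("SimpleSlopes (df = %d)\n", object@df))
  print(object@slopes, row.names = FALSE, digits = 3)
})
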