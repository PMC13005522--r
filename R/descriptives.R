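#' Intraindividual mean (iM)
#'
#' A person's own average of a diary variable across their observed
#' days.
#'
#' @param series a [PersonSeries-class].
#' @param variable variable name.
#' @return The iM.
#' @export
intraMean <- function(series, variable) {
  if (!variable %in% colnames(series@values))
    stop("unknown variable: ", variable)
  x <- series@values[series@observed[, variable], variable]
  if (!length(x)) stop("no observed days for '", variable, "'")
  mean(x)
}

#' Intraindividual standard deviation (iSD)
#'
#' A person's variability around their own iM across observed days.
#' Uses the sample (n - 1) denominator by default; `population = TRUE`
#' switches to the n denominator for sensitivity checks.
#'
#' @param series a [PersonSeries-class].
#' @param variable variable name.
#' @param population use the population (n) denominator?
#' @return The iSD.
#' @export
intraSD <- function(series, variable, population = FALSE) {
  if (!variable %in% colnames(series@values))
    stop("unknown variable: ", variable)
  x <- series@values[series@observed[, variable], variable]
  if (length(x) < 2L)
    stop("need at least 2 observed days for '", variable, "'")
  s <- stats::sd(x)
  if (population) s <- s * sqrt((length(x) - 1) / length(x))
  s
}

#' Classify intraindividual variability
#'
#' Classifies an iSD as `low` (below `lowMax`), `high` (above
#' `highMin`) or `mid`. The default thresholds 0.21 and 0.50 are the
#' gender-expression variability boundaries used to select the
#' illustrative menopause-study participants; they are
#' sample-selection devices, not universal cutoffs, and are
#' configurable.
#'
#' @param iSD numeric vector of iSD values.
#' @param lowMax upper bound (exclusive) of the low class.
#' @param highMin lower bound (exclusive) of the high class.
#' @return Character vector in `{"low", "mid", "high"}`.
#' @examples
#' classifyVariability(c(0.15, 0.35, 0.55))
#' @export
classifyVariability <- function(iSD, lowMax = 0.21, highMin = 0.50) {
  if (!(lowMax < highMin)) stop("'lowMax' must be below 'highMin'")
  out <- rep("mid", length(iSD))
  out[iSD < lowMax] <- "low"
  out[iSD > highMin] <- "high"
  out
}

#' Count days on which one variable dominates another
#'
#' Number of days with both variables observed and `a` strictly
#' greater than `b` (e.g. days when self-perceived masculinity
#' exceeded femininity).
#'
#' @param series a [PersonSeries-class].
#' @param a,b variable names.
#' @return Integer count.
#' @export
daysDominant <- function(series, a, b) {
  unknown <- setdiff(c(a, b), colnames(series@values))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  both <- series@observed[, a] & series@observed[, b]
  sum(series@values[both, a] > series@values[both, b])
}

#' Summarize one person's intraindividual descriptives
#'
#' @param series a [PersonSeries-class].
#' @param variables variables to summarize.
#' @param lowMax,highMin variability-class thresholds (see
#'   [classifyVariability()]).
#' @return data.frame with columns person_id, variable, iM, iSD,
#'   n_days, variability_class.
#' @export
summarizePerson <- function(series, variables = seriesVariables(series),
                            lowMax = 0.21, highMin = 0.50) {
  rows <- lapply(variables, function(v) {
    isd <- intraSD(series, v)
    data.frame(
      person_id = series@personId, variable = v,
      iM = intraMean(series, v), iSD = isd,
      n_days = sum(series@observed[, v]),
      variability_class = classifyVariability(isd, lowMax, highMin),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize every person in a study
#'
#' @param study a [DailyStudy-class].
#' @param variables variables to summarize (default: all variables of
#'   each person).
#' @param lowMax,highMin variability-class thresholds.
#' @return data.frame of stacked [summarizePerson()] rows.
#' @export
summarizeStudy <- function(study, variables = NULL, lowMax = 0.21,
                           highMin = 0.50) {
  rows <- lapply(study@persons, function(p)
    summarizePerson(p, variables %||% seriesVariables(p), lowMax, highMin))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-person plot data for a diary variable
#'
#' Day-level values together with the iM and the iM +/- 1 iSD band,
#' as a tidy table for external plotting.
#'
#' @param series a [PersonSeries-class].
#' @param variable variable name.
#' @return data.frame with columns day, value, iM, lower, upper.
#' @export
personPlotData <- function(series, variable) {
  m <- intraMean(series, variable)
  s <- intraSD(series, variable)
  data.frame(day = series@day,
             value = series@values[, variable],
             iM = m, lower = m - s, upper = m + s)
}
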