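#' Standard diary scales
#'
#' The scale metadata of the daily-diary variables used across the
#' three illustrative designs: SRIS femininity/masculinity composites
#' (1--5), SMFQ depressive-symptom composite (0--2), UPPS-P sensation
#' seeking composite (1--4), and the 0--5 integer delayed verbal
#' recall score.
#'
#' @return Named list of [ScaleSpec-class] objects.
#' @export
defaultDiaryScales <- function() {
  list(
    masculinity = scaleSpec("masculinity", 1, 5),
    femininity = scaleSpec("femininity", 1, 5),
    depression = scaleSpec("depression", 0, 2),
    sensation_seeking = scaleSpec("sensation_seeking", 1, 4),
    recall = scaleSpec("recall", 0, 5, integerValued = TRUE)
  )
}

#' Unbounded scale metadata for continuous series
#'
#' Convenience schema for reading back continuous (non-discretized)
#' simulated diaries, where values are not confined to a Likert range.
#'
#' @param variables variable names.
#' @return Named list of unbounded [ScaleSpec-class] objects.
#' @export
continuousScales <- function(variables) {
  out <- lapply(variables, function(v) scaleSpec(v, -Inf, Inf))
  names(out) <- variables
  out
}

#' Read a long-format daily-diary CSV
#'
#' Expects a header row with columns `person_id`, `day`, optionally
#' `phase`, and one column per variable; empty cells are missing. Each
#' person's rows are expanded onto the full day grid `1..T` (skipped
#' days become fully missing rows), so day indices are calendar
#' positions: day 4 after day 2 is not day 3's successor.
#'
#' @param path CSV file path.
#' @param schema named list of [ScaleSpec-class] objects describing
#'   the variable columns to read; values outside a scale's range are
#'   rejected.
#' @param studyLength nominal diary length T; defaults to the largest
#'   day index in the file.
#' @return A [DailyStudy-class].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("person_id,day,femininity", "p1,1,3.5", "p1,2,4"), tmp)
#' readDiary(tmp, list(femininity = scaleSpec("femininity", 1, 5)))
#' @export
readDiary <- function(path, schema, studyLength = NULL) {
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("person_id", "day")
  if (!all(need %in% names(raw)))
    stop("malformed CSV: missing required column(s) ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  vars <- names(schema)
  absent <- setdiff(vars, names(raw))
  if (length(absent))
    stop("malformed CSV: schema variable(s) not found: ",
         paste(absent, collapse = ", "))
  day <- suppressWarnings(as.integer(raw$day))
  bad <- which(is.na(day) | day < 1L)
  if (length(bad))
    stop("malformed CSV: non-positive or non-integer day at row ", bad[1L])
  pid <- as.character(raw$person_id)
  dup <- duplicated(paste(pid, day))
  if (any(dup))
    stop("duplicate (person, day) row: person '", pid[which(dup)[1L]],
         "', day ", day[which(dup)[1L]])
  for (v in vars) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    txt <- !is.na(raw[[v]]) & is.na(x)
    if (any(txt))
      stop("malformed CSV: non-numeric value for '", v, "' at row ",
           which(txt)[1L])
    sc <- schema[[v]]
    out <- !is.na(x) & (x < sc@min | x > sc@max)
    if (any(out)) {
      i <- which(out)[1L]
      stop(sprintf(
        "validation error: person '%s', day %d, variable '%s' = %g outside [%g, %g]",
        pid[i], day[i], v, x[i], sc@min, sc@max))
    }
    raw[[v]] <- x
  }
  hasPhase <- "phase" %in% names(raw)
  if (hasPhase) {
    ph <- suppressWarnings(as.integer(raw$phase))
    if (any(!is.na(ph) & !(ph %in% c(0L, 1L))))
      stop("validation error: 'phase' must be 0 or 1")
    raw$phase <- ph
  }
  T <- as.integer(studyLength %||% max(day))
  if (any(day > T))
    stop("validation error: day index exceeds studyLength ", T)
  persons <- lapply(split(seq_len(nrow(raw)), pid), function(rows) {
    values <- matrix(NA_real_, T, length(vars),
                     dimnames = list(NULL, vars))
    values[day[rows], ] <- as.matrix(raw[rows, vars, drop = FALSE])
    phase <- NULL
    if (hasPhase) {
      phase <- rep(NA_integer_, T)
      phase[day[rows]] <- raw$phase[rows]
    }
    personSeries(pid[rows[1L]], values, day = seq_len(T), phase = phase,
                 scales = schema)
  })
  dailyStudy(persons[order(names(persons))], studyLength = T)
}

#' Write a study to the long diary CSV dialect
#'
#' Values are printed with 17 significant digits so a read-back
#' reproduces the doubles and masks exactly. A JSON sidecar with the
#' [ScaleSpec-class] metadata is written alongside unless
#' `schemaPath = NA`.
#'
#' @param study a [DailyStudy-class].
#' @param path output CSV path.
#' @param schemaPath path of the JSON scale sidecar; default
#'   `<path>.scales.json`, `NA` to skip.
#' @return `path`, invisibly.
#' @export
writeDiary <- function(study, path,
                       schemaPath = paste0(path, ".scales.json")) {
  rows <- lapply(study@persons, function(p) {
    df <- data.frame(person_id = p@personId, day = p@day,
                     stringsAsFactors = FALSE)
    if (!is.null(p@phase))
      df$phase <- ifelse(is.na(p@phase), "", as.character(p@phase))
    for (v in colnames(p@values)) df[[v]] <- .formatNumeric(p@values[, v])
    df
  })
  allNames <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (nm in setdiff(allNames, names(df))) df[[nm]] <- ""
    df[, allNames, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.na(schemaPath)) {
    scales <- list()
    for (p in study@persons)
      for (nm in names(p@scales)) scales[[nm]] <- p@scales[[nm]]
    meta <- lapply(scales, function(sc) list(
      name = sc@name, min = sc@min, max = sc@max,
      integer_valued = sc@integerValued, items = as.list(sc@items)))
    jsonlite::write_json(meta, schemaPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a scale-metadata JSON sidecar
#'
#' @param path JSON path as written by [writeDiary()].
#' @return Named list of [ScaleSpec-class] objects.
#' @export
readScaleSchema <- function(path) {
  meta <- jsonlite::read_json(path)
  out <- lapply(meta, function(m)
    scaleSpec(m$name, m$min, m$max, isTRUE(m$integer_valued),
              unlist(m$items) %||% character()))
  names(out) <- vapply(out, function(s) s@name, character(1))
  out
}

#' Average item scores into a daily composite
#'
#' Adds a composite column equal to the per-day arithmetic mean of the
#' item columns (e.g. the three SRIS femininity items). By default the
#' composite is missing on a day if any constituent item is missing
#' that day; `rule = "available"` instead averages the items observed
#' that day.
#'
#' @param series a [PersonSeries-class].
#' @param items character vector of item column names; all items must
#'   share one scale.
#' @param outName name of the new composite column.
#' @param rule `"all"` (default) or `"available"` missing-day rule.
#' @return The series with the composite appended (and its
#'   [ScaleSpec-class] registered).
#' @export
computeComposite <- function(series, items, outName,
                             rule = c("all", "available")) {
  rule <- match.arg(rule)
  unknown <- setdiff(items, colnames(series@values))
  if (length(unknown))
    stop("unknown item name(s): ", paste(unknown, collapse = ", "))
  specs <- series@scales[items]
  if (any(vapply(specs, is.null, logical(1))))
    stop("all items must have scale metadata")
  rng <- unique(t(vapply(specs, function(s) c(s@min, s@max), numeric(2))))
  if (nrow(rng) != 1L)
    stop("all items must share one scale")
  x <- series@values[, items, drop = FALSE]
  if (rule == "all") {
    comp <- rowMeans(x)
  } else {
    comp <- rowMeans(x, na.rm = TRUE)
    comp[is.nan(comp)] <- NA_real_
  }
  values <- cbind(series@values, comp)
  colnames(values) <- c(colnames(series@values), outName)
  scales <- series@scales
  scales[[outName]] <- scaleSpec(outName, rng[1L, 1L], rng[1L, 2L],
                                 integerValued = FALSE, items = items)
  out <- personSeries(series@personId, values, day = series@day,
                      phase = series@phase, scales = scales)
  out
}

#' Diary response rate of a variable
#'
#' Fraction of the nominal study days on which the variable was
#' observed; the >= 80% field standard is the usual inclusion bar.
#'
#' @param series a [PersonSeries-class].
#' @param variable variable name.
#' @return Fraction in `[0, 1]`.
#' @export
responseRate <- function(series, variable) {
  if (!variable %in% colnames(series@values))
    stop("unknown variable: ", variable)
  sum(series@observed[, variable]) / length(series@day)
}

#' Filter a study by diary compliance
#'
#' Retains persons whose response rate is at least `minRate` on every
#' analysis variable (the boundary is inclusive: 0.80 with the default
#' threshold is kept). One message is emitted per excluded person.
#'
#' @param study a [DailyStudy-class].
#' @param minRate minimum response rate (default 0.80).
#' @param variables variables to check; default all variables.
#' @return The filtered [DailyStudy-class].
#' @export
filterCompliance <- function(study, minRate = 0.80, variables = NULL) {
  keep <- vapply(study@persons, function(p) {
    vars <- variables %||% colnames(p@values)
    rates <- vapply(vars, function(v) responseRate(p, v), numeric(1))
    if (all(rates >= minRate)) return(TRUE)
    worst <- which.min(rates)
    message(sprintf(
      "excluding person '%s': response rate %.3f on '%s' below %.2f",
      p@personId, rates[worst], vars[worst], minRate))
    FALSE
  }, logical(1))
  new("DailyStudy", persons = study@persons[keep],
      studyLength = study@studyLength)
}

#' Lag-embed a person series for temporal-network estimation
#'
#' Builds the complete-pair design for next-day models: one row per
#' consecutive day pair `(t - lag, t)` in which both days exist on the
#' calendar grid and all requested variables are observed on both
#' days. Columns are the lagged block (`<var>_lag`) followed by the
#' current block.
#'
#' @param series a [PersonSeries-class].
#' @param variables variables to embed.
#' @param lag lag in days (only 1 is used by the network stage).
#' @param minPairs minimum number of complete pairs below which an
#'   "insufficient complete pairs" error is raised (default 10, a
#'   safety rail for the estimation stages; lower it for toy data).
#' @return List with `data` (N x 2p matrix), `N` (complete-pair
#'   count), and `variables`.
#' @export
lagEmbed <- function(series, variables, lag = 1L, minPairs = 10L) {
  lag <- .assertCount(lag, "lag")
  unknown <- setdiff(variables, colnames(series@values))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  T <- length(series@day)
  if (T <= lag) stop("series shorter than lag")
  dayPos <- match(seq_len(max(series@day)), series@day)
  obs <- series@observed[, variables, drop = FALSE]
  rowOK <- rowSums(obs) == length(variables)
  pairs <- list()
  for (t in (lag + 1L):max(series@day)) {
    iNow <- dayPos[t]
    iPast <- dayPos[t - lag]
    if (is.na(iNow) || is.na(iPast)) next
    if (rowOK[iNow] && rowOK[iPast]) pairs[[length(pairs) + 1L]] <- c(iPast, iNow)
  }
  N <- length(pairs)
  if (N < minPairs)
    stop("insufficient complete pairs: ", N, " < ", minPairs)
  idx <- do.call(rbind, pairs)
  mat <- cbind(series@values[idx[, 1L], variables, drop = FALSE],
               series@values[idx[, 2L], variables, drop = FALSE])
  colnames(mat) <- c(paste0(variables, "_lag"), variables)
  list(data = mat, N = N, variables = variables)
}

#' Column-standardize a matrix
#'
#' z-scores each column using the sample SD (denominator N - 1) and
#' records the invertible transform.
#'
#' @param m numeric matrix; every column must have positive SD.
#' @return List with `scaled`, `center`, `scale`.
#' @seealso [unstandardizeColumns()]
#' @export
standardizeColumns <- function(m) {
  m <- as.matrix(m)
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  zero <- which(scale <= 0 | !is.finite(scale))
  if (length(zero))
    stop("zero-variance column: ",
         paste(colnames(m)[zero] %||% zero, collapse = ", "))
  scaled <- sweep(sweep(m, 2L, center), 2L, scale, "/")
  list(scaled = scaled, center = center, scale = scale)
}

#' Invert a column standardization
#'
#' @param z a list as returned by [standardizeColumns()] (optionally
#'   with a replaced `scaled` matrix).
#' @return The matrix on the original scale.
#' @export
unstandardizeColumns <- function(z) {
  sweep(sweep(z$scaled, 2L, z$scale, "*"), 2L, z$center, "+")
}
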