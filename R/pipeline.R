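# Workflow orchestration: the three analysis stages as batch commands
# over a diary CSV, plus the simulator front-end. Each
# command is deterministic given its inputs, isolates per-person
# failures, and records every per-person decision as a log line.

.logLine <- function(...) message(sprintf(...))

#' Build a SimConfig from a plain list (e.g. parsed JSON)
#'
#' Accepts the JSON-friendly representation used by the command-line
#' wrapper: scalar fields plus row-major matrices for the truth.
#'
#' @param x named list with elements `n_days`, `n_persons`,
#'   `variables`, `regimen` (list with `kind` and optional regimen
#'   fields), `truth` (list with `A`, `Phi`, `Psi`, optional
#'   `intercepts`, `slope_base`, `slope_phase_shift`, `recall_ar`,
#'   `recall_noise_sd`, `missing_rate`, `seed`), and optional
#'   `discretize`, `recall_variable`, `fem_variable`.
#' @return A [SimConfig-class].
#' @export
simConfigFromList <- function(x) {
  asMat <- function(m) {
    if (is.matrix(m)) return(m)
    do.call(rbind, lapply(m, unlist))
  }
  tr <- x$truth
  p <- length(x$variables)
  truth <- simTruth(
    A = asMat(tr$A), Phi = asMat(tr$Phi),
    Psi = if (is.null(tr$Psi)) diag(p) else asMat(tr$Psi),
    intercepts = unlist(tr$intercepts) %||% numeric(p),
    slopeBase = tr$slope_base %||% 0,
    slopePhaseShift = tr$slope_phase_shift %||% 0,
    recallAR = tr$recall_ar %||% 0.3,
    recallNoiseSD = tr$recall_noise_sd %||% 0.5,
    missingRate = tr$missing_rate %||% 0,
    seed = tr$seed %||% 1L)
  rg <- x$regimen %||% list(kind = "natural_cycle")
  regimen <- phaseRegimen(
    kind = rg$kind %||% "natural_cycle",
    cycleLength = rg$cycle_length_days %||% 28L,
    bleedDays = rg$bleed_days %||% 5L,
    activeDays = rg$active_days %||% 21L,
    inactiveDays = rg$inactive_days %||% 7L,
    periRange = unlist(rg$peri_cycle_length_range) %||% c(21L, 60L))
  simConfig(truth, nDays = x$n_days %||% 100L,
            varNames = unlist(x$variables),
            regimen = regimen,
            discretize = isTRUE(x$discretize),
            nPersons = x$n_persons %||% 1L,
            recallVariable = x$recall_variable %||% NA_character_,
            femVariable = x$fem_variable %||% "femininity")
}

#' Simulate a study and write it to disk
#'
#' Runs [simulateStudy()], writes the diary CSV (plus its scale
#' sidecar) and the ground-truth JSON, and logs the seed and file
#' digests.
#'
#' @param config a [SimConfig-class] (or list accepted by
#'   [simConfigFromList()]).
#' @param outDir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
runSimulate <- function(config, outDir) {
  if (!is(config, "SimConfig")) config <- simConfigFromList(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateStudy(config)
  csv <- file.path(outDir, "diary.csv")
  truthPath <- file.path(outDir, "truth.json")
  writeDiary(sim$study, csv)
  writeTruth(sim$truth, truthPath)
  .logLine("seed: %d", config@truth@seed)
  for (f in c(csv, truthPath))
    .logLine("wrote %s (md5 %s)", f, unname(tools::md5sum(f)))
  invisible(list(csv = csv, truth = truthPath))
}

#' Intraindividual descriptives for every compliant person
#'
#' Applies the compliance filter, optionally builds item composites,
#' and writes one iM/iSD/variability-class row per person and
#' variable.
#'
#' @param inCsv diary CSV path.
#' @param outCsv output CSV path.
#' @param schema named list of [ScaleSpec-class] (default
#'   [defaultDiaryScales()] restricted to the file's columns).
#' @param variables variables to summarize (default: all schema
#'   variables).
#' @param minRate compliance threshold (default 0.80).
#' @param lowMax,highMin variability-class thresholds.
#' @param composites optional named list: composite name -> item
#'   names, built with [computeComposite()] before summarizing.
#' @return The summary data.frame, invisibly.
#' @export
runDescribe <- function(inCsv, outCsv, schema = NULL, variables = NULL,
                        minRate = 0.80, lowMax = 0.21, highMin = 0.50,
                        composites = NULL) {
  schema <- schema %||% .schemaForFile(inCsv)
  study <- readDiary(inCsv, schema)
  study <- filterCompliance(study, minRate = minRate,
                            variables = variables)
  if (!nPersons(study)) {
    warning("no persons retained after compliance filtering")
    out <- data.frame(person_id = character(), variable = character(),
                      iM = numeric(), iSD = numeric(),
                      n_days = integer(), variability_class = character())
  } else {
    if (!is.null(composites))
      study@persons <- lapply(study@persons, function(p) {
        for (nm in names(composites))
          p <- computeComposite(p, composites[[nm]], nm)
        p
      })
    out <- summarizeStudy(study, variables = variables,
                          lowMax = lowMax, highMin = highMin)
  }
  utils::write.csv(out, outCsv, row.names = FALSE)
  invisible(out)
}

#' Moderated regression for every person in a diary CSV
#'
#' Runs the residualized femininity-by-phase regression separately for
#' each person, writing a Table-1-style coefficient CSV (term, b, SE,
#' p, reference level) and a simple-slopes JSON. One person's failure
#' (e.g. constant phase) never aborts the batch; it is logged and the
#' person is marked failed in the outputs.
#'
#' @param inCsv diary CSV path (must contain a `phase` column).
#' @param outCsv coefficient-table CSV path.
#' @param outJson simple-slopes JSON path (default `<outCsv>.json`).
#' @param outcome,predictor variable names (defaults `"recall"`,
#'   `"femininity"`).
#' @param schema named list of [ScaleSpec-class].
#' @param minRate compliance threshold applied to outcome and
#'   predictor (default 0.80).
#' @return List of per-person results, invisibly.
#' @export
runRegress <- function(inCsv, outCsv, outJson = paste0(outCsv, ".json"),
                       outcome = "recall", predictor = "femininity",
                       schema = NULL, minRate = 0.80) {
  schema <- schema %||% .schemaForFile(inCsv)
  study <- readDiary(inCsv, schema)
  study <- filterCompliance(study, minRate = minRate,
                            variables = c(outcome, predictor))
  results <- list()
  rows <- list()
  slopes <- list()
  for (id in personIds(study)) {
    res <- tryCatch(
      runModeratedRegression(getPerson(study, id), outcome = outcome,
                             predictor = predictor),
      error = function(e) e)
    if (inherits(res, "error")) {
      .logLine("person '%s' failed: %s", id, conditionMessage(res))
      rows[[id]] <- data.frame(person_id = id, term = NA_character_,
                               b = NA_real_, SE = NA_real_, p = NA_real_,
                               reference_level = NA_character_,
                               status = "failed", stringsAsFactors = FALSE)
      slopes[[id]] <- list(status = "failed",
                           error = conditionMessage(res))
    } else {
      results[[id]] <- res
      tab <- coefficientTable(res$result)
      tab$status <- "ok"
      rows[[id]] <- tab
      slopes[[id]] <- list(status = "ok",
                           slopes = res$slopes@slopes,
                           df = res$slopes@df,
                           report = res$report)
    }
  }
  utils::write.csv(do.call(rbind, rows), outCsv, row.names = FALSE)
  jsonlite::write_json(slopes, outJson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(results)
}

#' Person-specific temporal networks for a diary CSV
#'
#' For each compliant person: z-score, lag-embed, run the
#' Lagrange-multiplier [forwardSearch()], and export the network edge
#' list and fit/trace report. Persons with too few complete day pairs
#' are skipped with a message; one person's estimation failure never
#' aborts the batch.
#'
#' @param inCsv diary CSV path.
#' @param outDir output directory for `<person>_network.csv` (+
#'   `.json`) files.
#' @param variables network variables (default the four adolescent
#'   diary variables).
#' @param schema named list of [ScaleSpec-class].
#' @param minRate compliance threshold (default 0.80).
#' @param alpha,prune,maxSteps search options, see [forwardSearch()].
#' @return Named list of per-person search results, invisibly.
#' @export
runNetwork <- function(inCsv, outDir,
                       variables = c("masculinity", "femininity",
                                     "depression", "sensation_seeking"),
                       schema = NULL, minRate = 0.80, alpha = 0.05,
                       prune = TRUE, maxSteps = NULL) {
  schema <- schema %||% .schemaForFile(inCsv)
  study <- readDiary(inCsv, schema)
  study <- filterCompliance(study, minRate = minRate,
                            variables = variables)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (id in personIds(study)) {
    res <- tryCatch({
      emb <- lagEmbed(getPerson(study, id), variables)
      z <- standardizeColumns(emb$data)
      forwardSearch(z$scaled, N = emb$N, varNames = variables,
                    alpha = alpha, prune = prune, maxSteps = maxSteps)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      .logLine("person '%s' skipped: %s", id, conditionMessage(res))
      next
    }
    csv <- file.path(outDir, paste0(id, "_network.csv"))
    exportNetwork(res$model, csv, trace = res$trace, pruned = prune)
    .logLine("person '%s': %d edges, stop reason %s, %d/4 excellent",
             id, nrow(networkEdges(res$model)), res$trace@stopReason,
             res$model@fit@nExcellent)
    out[[id]] <- res
  }
  invisible(out)
}

# restrict the standard scales to the columns actually present
.schemaForFile <- function(path) {
  head <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  sc <- defaultDiaryScales()
  found <- intersect(names(sc), head)
  if (!length(found))
    stop("no known diary variables in '", path,
         "'; provide an explicit schema")
  sc[found]
}
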