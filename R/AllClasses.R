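#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Measurement scale metadata for a diary variable
#'
#' Describes the bounded response scale of one daily-diary variable:
#' its admissible range, whether responses are integer-valued (e.g. a
#' 0--5 recall count) and, for composites, the item names it averages.
#'
#' @slot name variable name.
#' @slot min,max scale bounds; all stored observations must lie in
#'   `[min, max]`.
#' @slot integerValued logical; `TRUE` for integer response scales.
#' @slot items character vector of constituent item names (empty for
#'   variables that are recorded directly).
#'
#' @seealso [scaleSpec()]
#' @export
setClass("ScaleSpec",
  representation(
    name = "character",
    min = "numeric",
    max = "numeric",
    integerValued = "logical",
    items = "character"
  )
)

setValidity("ScaleSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@min) != 1L || length(object@max) != 1L)
    msg <- c(msg, "'min' and 'max' must be single numbers")
  else if (!(object@min < object@max))
    msg <- c(msg, "'min' must be strictly less than 'max'")
  if (length(object@integerValued) != 1L)
    msg <- c(msg, "'integerValued' must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct a ScaleSpec
#'
#' @param name variable name.
#' @param min,max numeric scale bounds (`min < max`).
#' @param integerValued logical; integer response scale?
#' @param items character vector of constituent items, if the variable
#'   is a composite.
#' @return A [ScaleSpec-class] object.
#' @examples
#' scaleSpec("femininity", 1, 5)
#' scaleSpec("recall", 0, 5, integerValued = TRUE)
#' @export
scaleSpec <- function(name, min, max, integerValued = FALSE,
                      items = character()) {
  new("ScaleSpec", name = name, min = as.numeric(min),
      max = as.numeric(max), integerValued = integerValued,
      items = as.character(items))
}

#' One person's daily-diary time series
#'
#' Holds a single participant's person-day observations on a fixed day
#' grid `1..T`: a day-by-variable value matrix, a parallel logical
#' observation mask (a value is present iff its mask entry is `TRUE`),
#' an optional per-day binary hormone-milieu phase indicator
#' (1 = low milieu: bleeding or inactive pill; 0 = high milieu), and
#' per-variable [ScaleSpec-class] metadata.
#'
#' @slot personId participant identifier.
#' @slot day integer day index, strictly increasing, no duplicates.
#' @slot values numeric matrix, days x variables; `NA` where unobserved.
#' @slot observed logical matrix, same shape as `values`.
#' @slot phase integer vector of 0/1 per day (NA on unobserved days),
#'   or `NULL` when the study records no phase.
#' @slot scales named list of [ScaleSpec-class], one per variable.
#'
#' @seealso [personSeries()], [DailyStudy-class]
#' @export
setClass("PersonSeries",
  representation(
    personId = "character",
    day = "integer",
    values = "matrix",
    observed = "matrix",
    phase = "integerOrNULL",
    scales = "list"
  )
)

setValidity("PersonSeries", function(object) {
  msg <- character()
  d <- object@day
  v <- object@values
  m <- object@observed
  if (length(object@personId) != 1L)
    msg <- c(msg, "'personId' must be a single string")
  if (length(d) == 0L || any(diff(d) <= 0L))
    msg <- c(msg, "'day' must be non-empty and strictly increasing")
  if (!identical(dim(v), dim(m)))
    msg <- c(msg, "'values' and 'observed' must have identical dimensions")
  if (nrow(v) != length(d))
    msg <- c(msg, "'values' must have one row per day")
  if (is.null(colnames(v)) || any(!nzchar(colnames(v))))
    msg <- c(msg, "'values' must have non-empty column names")
  if (!is.logical(m))
    msg <- c(msg, "'observed' must be logical")
  if (identical(dim(v), dim(m)) && is.logical(m)) {
    if (any(is.na(v[m])))
      msg <- c(msg, "observed cells must not be NA")
    if (any(!is.na(v[!m])))
      msg <- c(msg, "unobserved cells must be NA")
  }
  if (!is.null(object@phase)) {
    ph <- object@phase
    if (length(ph) != length(d))
      msg <- c(msg, "'phase' must have one entry per day")
    if (any(!(ph[!is.na(ph)] %in% c(0L, 1L))))
      msg <- c(msg, "'phase' entries must be 0 or 1 (or NA on missed days)")
  }
  if (length(object@scales)) {
    known <- names(object@scales)
    for (var in colnames(v)) {
      if (!var %in% known) next
      sc <- object@scales[[var]]
      x <- v[m[, var], var]
      if (length(x) && (any(x < sc@min) || any(x > sc@max)))
        msg <- c(msg, sprintf(
          "values of '%s' outside scale range [%g, %g]", var, sc@min, sc@max))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PersonSeries
#'
#' @param personId participant identifier.
#' @param values numeric day-by-variable matrix (`NA` = missing).
#' @param day integer day indices (default `1:nrow(values)`).
#' @param phase optional per-day 0/1 hormone-milieu indicator.
#' @param scales named list of [ScaleSpec-class] objects.
#' @return A [PersonSeries-class] object.
#' @export
personSeries <- function(personId, values, day = seq_len(nrow(values)),
                         phase = NULL, scales = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  observed <- !is.na(values)
  if (!is.null(phase)) phase <- as.integer(phase)
  new("PersonSeries", personId = personId, day = as.integer(day),
      values = values, observed = observed, phase = phase,
      scales = scales)
}

#' A multi-person daily-diary study
#'
#' @slot persons named list of [PersonSeries-class]; names are the
#'   person identifiers.
#' @slot studyLength nominal number of diary days; all person day
#'   indices must be `<= studyLength`.
#' @seealso [dailyStudy()], [readDiary()]
#' @export
setClass("DailyStudy",
  representation(
    persons = "list",
    studyLength = "integer"
  )
)

setValidity("DailyStudy", function(object) {
  msg <- character()
  ok <- vapply(object@persons, is, logical(1), "PersonSeries")
  if (!all(ok))
    msg <- c(msg, "'persons' must be a list of PersonSeries")
  else {
    ids <- vapply(object@persons, function(p) p@personId, character(1))
    if (!identical(as.character(names(object@persons)), unname(ids)))
      msg <- c(msg, "names of 'persons' must match personId slots")
    if (any(vapply(object@persons,
                   function(p) max(p@day) > object@studyLength, logical(1))))
      msg <- c(msg, "all day indices must be <= studyLength")
  }
  if (length(object@studyLength) != 1L || object@studyLength < 1L)
    msg <- c(msg, "'studyLength' must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a DailyStudy
#'
#' @param persons list of [PersonSeries-class] objects.
#' @param studyLength nominal number of diary days; defaults to the
#'   largest day index present.
#' @return A [DailyStudy-class] object.
#' @export
dailyStudy <- function(persons,
                       studyLength = max(vapply(persons,
                                                function(p) max(p@day),
                                                integer(1)), 1L)) {
  names(persons) <- vapply(persons, function(p) p@personId, character(1))
  new("DailyStudy", persons = persons, studyLength = as.integer(studyLength))
}

## ---- synthetic-data classes -------------------------------------------

#' Hormone-phase regimen for phase-sequence simulation
#'
#' Encodes how the daily binary hormone-milieu indicator is generated:
#' a natural menstrual cycle (bleeding days at the start of each
#' cycle), an oral-contraceptive pack (inactive pill days), or a
#' menopause stage (pre: regular cycles; peri: irregular cycle lengths
#' drawn uniformly from a range; post: no low-milieu days).
#'
#' @slot kind one of `"natural_cycle"`, `"oc_regimen"`,
#'   `"menopause_pre"`, `"menopause_peri"`, `"menopause_post"`.
#' @slot cycleLength natural-cycle length in days (default 28).
#' @slot bleedDays bleeding days at cycle onset (default 5).
#' @slot activeDays,inactiveDays OC pack composition (defaults 21/7).
#' @slot periRange two integers: uniform range of perimenopausal cycle
#'   lengths.
#' @seealso [phaseRegimen()], [simulatePhaseSequence()]
#' @export
setClass("PhaseRegimen",
  representation(
    kind = "character",
    cycleLength = "integer",
    bleedDays = "integer",
    activeDays = "integer",
    inactiveDays = "integer",
    periRange = "integer"
  )
)

.regimenKinds <- c("natural_cycle", "oc_regimen", "menopause_pre",
                   "menopause_peri", "menopause_post")

setValidity("PhaseRegimen", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .regimenKinds)
    msg <- c(msg, paste0("'kind' must be one of: ",
                         paste(.regimenKinds, collapse = ", ")))
  if (object@bleedDays >= object@cycleLength)
    msg <- c(msg, "'bleedDays' must be less than 'cycleLength'")
  if (object@activeDays < 1L || object@inactiveDays < 1L)
    msg <- c(msg, "OC pack must have at least one active and one inactive day")
  if (length(object@periRange) != 2L ||
      object@periRange[1L] > object@periRange[2L])
    msg <- c(msg, "'periRange' must be an increasing integer pair")
  if (object@periRange[1L] <= object@bleedDays)
    msg <- c(msg, "'periRange' lengths must exceed 'bleedDays'")
  if (length(msg)) msg else TRUE
})

#' Construct a PhaseRegimen
#'
#' @param kind regimen kind (see [PhaseRegimen-class]).
#' @param cycleLength,bleedDays natural-cycle parameters.
#' @param activeDays,inactiveDays OC pack composition.
#' @param periRange perimenopausal cycle-length range (days).
#' @return A [PhaseRegimen-class] object.
#' @examples
#' phaseRegimen("oc_regimen")                 # 21 active / 7 inactive
#' phaseRegimen("menopause_peri", periRange = c(21, 60))
#' @export
phaseRegimen <- function(kind = "natural_cycle", cycleLength = 28L,
                         bleedDays = 5L, activeDays = 21L,
                         inactiveDays = 7L, periRange = c(21L, 60L)) {
  new("PhaseRegimen", kind = kind, cycleLength = as.integer(cycleLength),
      bleedDays = as.integer(bleedDays), activeDays = as.integer(activeDays),
      inactiveDays = as.integer(inactiveDays),
      periRange = as.integer(periRange))
}

#' Ground-truth generator parameters for a synthetic diary study
#'
#' The structural-VAR truth paired with every synthetic dataset:
#' contemporaneous matrix `A` (entry `[i, j]` is the same-day effect of
#' variable `j` on variable `i`; zero diagonal), lagged matrix `Phi`
#' (entry `[i, j]` is the next-day effect of `j` on `i`), residual
#' covariance `Psi`, plus the phase-moderated recall slopes and the
#' diary-compliance missingness rate.
#'
#' @slot A,Phi,Psi p x p coefficient / covariance matrices.
#' @slot intercepts length-p structural intercepts.
#' @slot slopeBase recall slope on femininity in the high milieu (s0).
#' @slot slopePhaseShift shift of that slope in the low milieu (s1);
#'   the low-milieu slope is `s0 + s1`.
#' @slot recallAR autoregressive coefficient of the recall series.
#' @slot recallNoiseSD recall innovation SD.
#' @slot missingRate whole-day MCAR missingness probability (<= 0.2,
#'   matching the >= 80% compliance standard).
#' @slot seed base simulation seed.
#' @seealso [simTruth()], [simulateStudy()]
#' @export
setClass("SimTruth",
  representation(
    A = "matrix",
    Phi = "matrix",
    Psi = "matrix",
    intercepts = "numeric",
    slopeBase = "numeric",
    slopePhaseShift = "numeric",
    recallAR = "numeric",
    recallNoiseSD = "numeric",
    missingRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  p <- nrow(object@A)
  if (ncol(object@A) != p || !identical(dim(object@Phi), dim(object@A)) ||
      !identical(dim(object@Psi), dim(object@A)))
    msg <- c(msg, "'A', 'Phi', 'Psi' must be square with identical dims")
  else {
    if (any(diag(object@A) != 0))
      msg <- c(msg, "'A' must have a zero diagonal")
    if (max(abs(object@Psi - t(object@Psi))) > 1e-10)
      msg <- c(msg, "'Psi' must be symmetric")
    else if (inherits(try(chol(object@Psi), silent = TRUE), "try-error"))
      msg <- c(msg, "'Psi' must be positive definite")
    IA <- diag(p) - object@A
    if (abs(det(IA)) < 1e-12)
      msg <- c(msg, "(I - A) must be invertible")
    else {
      ev <- abs(eigen(solve(IA, object@Phi), only.values = TRUE)$values)
      if (length(ev) && max(ev) >= 1)
        msg <- c(msg, "non-stationary truth: spectral radius of (I-A)^-1 Phi >= 1")
    }
    if (length(object@intercepts) != p)
      msg <- c(msg, "'intercepts' must have length p")
  }
  if (object@missingRate < 0 || object@missingRate > 0.2)
    msg <- c(msg, "'missingRate' must lie in [0, 0.2]")
  if (abs(object@recallAR) >= 1)
    msg <- c(msg, "'recallAR' must satisfy |ar| < 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimTruth
#'
#' @param A,Phi,Psi p x p matrices (see [SimTruth-class]); `Psi`
#'   defaults to the identity.
#' @param intercepts structural intercepts (default 0).
#' @param slopeBase,slopePhaseShift recall-moderation slopes s0, s1.
#' @param recallAR,recallNoiseSD recall dynamics parameters.
#' @param missingRate whole-day missingness probability in `[0, 0.2]`.
#' @param seed base simulation seed.
#' @return A [SimTruth-class] object.
#' @export
simTruth <- function(A, Phi, Psi = diag(nrow(A)),
                     intercepts = numeric(nrow(A)),
                     slopeBase = 0, slopePhaseShift = 0,
                     recallAR = 0.3, recallNoiseSD = 0.5,
                     missingRate = 0, seed = 1L) {
  new("SimTruth", A = A, Phi = Phi, Psi = Psi,
      intercepts = intercepts, slopeBase = slopeBase,
      slopePhaseShift = slopePhaseShift, recallAR = recallAR,
      recallNoiseSD = recallNoiseSD, missingRate = missingRate,
      seed = as.integer(seed))
}

#' Full configuration for a synthetic daily-diary study
#'
#' @slot nDays number of diary days T (>= 30).
#' @slot varNames names of the structural-VAR variables (columns of
#'   the truth matrices).
#' @slot scales named list of [ScaleSpec-class]; must cover every
#'   generated variable when `discretize = TRUE`.
#' @slot regimen the [PhaseRegimen-class] generating the phase days.
#' @slot truth the [SimTruth-class] generating the dynamics.
#' @slot discretize map latent continuous series onto the Likert
#'   scales (`TRUE`) or keep them continuous (`FALSE`).
#' @slot nPersons number of participants to generate.
#' @slot recallVariable name of the phase-moderated recall outcome, or
#'   `NA` to generate none.
#' @slot femVariable name of the VAR variable acting as the daily
#'   femininity predictor of recall.
#' @seealso [simConfig()], [simulateStudy()]
#' @export
setClass("SimConfig",
  representation(
    nDays = "integer",
    varNames = "character",
    scales = "list",
    regimen = "PhaseRegimen",
    truth = "SimTruth",
    discretize = "logical",
    nPersons = "integer",
    recallVariable = "character",
    femVariable = "character"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nDays < 30L)
    msg <- c(msg, "'nDays' must be at least 30")
  if (length(object@varNames) != nrow(object@truth@A))
    msg <- c(msg, "'varNames' must match the truth dimension p")
  if (!is.na(object@recallVariable) &&
      !object@femVariable %in% object@varNames)
    msg <- c(msg, "'femVariable' must be one of 'varNames'")
  if (object@nPersons < 1L)
    msg <- c(msg, "'nPersons' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults mirror the adolescent daily-diary design: the four
#' variables masculinity, femininity, depression and sensation seeking
#' observed over 100 days, with their published Likert scales.
#'
#' @param truth a [SimTruth-class].
#' @param nDays diary length T (default 100).
#' @param varNames VAR variable names.
#' @param scales named list of [ScaleSpec-class]; defaults supply the
#'   standard diary scales for the default variables.
#' @param regimen a [PhaseRegimen-class] (default natural cycle).
#' @param discretize discretize onto Likert scales? (default `FALSE`).
#' @param nPersons number of participants (default 1).
#' @param recallVariable name of the moderated recall outcome or
#'   `NA_character_` (default) for none.
#' @param femVariable VAR variable moderating recall (default
#'   `"femininity"`).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(truth, nDays = 100L,
                      varNames = c("masculinity", "femininity",
                                   "depression", "sensation_seeking"),
                      scales = NULL,
                      regimen = phaseRegimen("natural_cycle"),
                      discretize = FALSE, nPersons = 1L,
                      recallVariable = NA_character_,
                      femVariable = "femininity") {
  if (is.null(scales)) scales <- defaultDiaryScales()
  new("SimConfig", nDays = as.integer(nDays), varNames = varNames,
      scales = scales, regimen = regimen, truth = truth,
      discretize = discretize, nPersons = as.integer(nPersons),
      recallVariable = recallVariable, femVariable = femVariable)
}

## ---- uSEM classes -----------------------------------------------------

#' Free-parameter pattern of a hybrid uSEM
#'
#' Defines which structural parameters are estimated: contemporaneous
#' entries of `A` (directed same-day paths), off-diagonal entries of
#' the lagged matrix `Phi` (the diagonal autoregressions are always
#' free), and off-diagonal residual covariances in `Psi` (the diagonal
#' residual variances are always free). The covariance of the lagged
#' (exogenous) block is always saturated. Index pairs follow the
#' `A[i, j]` = effect of `j` on `i` convention.
#'
#' @slot p number of endogenous variables.
#' @slot varNames variable names.
#' @slot freeA k x 2 integer matrix of free `A` entries (rows `(i, j)`).
#' @slot freePhi k x 2 integer matrix of free off-diagonal `Phi`
#'   entries.
#' @slot freePsi k x 2 integer matrix of free `Psi` off-diagonal pairs
#'   (stored with `i < j`).
#' @seealso [usemSpec()], [fitUSEM()]
#' @export
setClass("USEMSpec",
  representation(
    p = "integer",
    varNames = "character",
    freeA = "matrix",
    freePhi = "matrix",
    freePsi = "matrix"
  )
)

setValidity("USEMSpec", function(object) {
  msg <- character()
  p <- object@p
  chk <- function(m, label) {
    if (nrow(m) && (ncol(m) != 2L || any(m < 1L) || any(m > p)))
      return(sprintf("'%s' must be a k x 2 matrix of indices in 1..p", label))
    NULL
  }
  msg <- c(msg, chk(object@freeA, "freeA"), chk(object@freePhi, "freePhi"),
           chk(object@freePsi, "freePsi"))
  if (nrow(object@freeA)) {
    if (any(object@freeA[, 1L] == object@freeA[, 2L]))
      msg <- c(msg, "'freeA' must not contain self-loops")
    keys <- paste(object@freeA[, 1L], object@freeA[, 2L])
    rev <- paste(object@freeA[, 2L], object@freeA[, 1L])
    if (any(rev %in% keys))
      msg <- c(msg, "'freeA' must not contain a reciprocal pair (identification rule)")
    if (anyDuplicated(keys))
      msg <- c(msg, "'freeA' contains duplicate entries")
  }
  if (nrow(object@freePhi) && any(object@freePhi[, 1L] == object@freePhi[, 2L]))
    msg <- c(msg, "'freePhi' lists off-diagonal entries only (diagonal is always free)")
  if (nrow(object@freePsi)) {
    if (any(object@freePsi[, 1L] >= object@freePsi[, 2L]))
      msg <- c(msg, "'freePsi' pairs must be stored with i < j")
    if (anyDuplicated(paste(object@freePsi[, 1L], object@freePsi[, 2L])))
      msg <- c(msg, "'freePsi' contains duplicate pairs")
  }
  if (length(object@varNames) != p)
    msg <- c(msg, "'varNames' must have length p")
  if (length(msg)) msg else TRUE
})

.indexMatrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(), 0L, 2L))
  m <- matrix(as.integer(x), ncol = 2L, byrow = is.null(dim(x)))
  if (!is.null(dim(x))) m <- matrix(as.integer(x), ncol = 2L)
  m
}

#' Construct a USEMSpec
#'
#' With all pattern arguments empty this is the null structural model
#' that starts the forward search: autoregressions and residual
#' variances only.
#'
#' @param p number of endogenous variables.
#' @param varNames variable names (default `V1..Vp`).
#' @param freeA,freePhi,freePsi integer index matrices (k x 2) of free
#'   entries; see [USEMSpec-class].
#' @return A [USEMSpec-class] object.
#' @examples
#' usemSpec(4)                                   # null structural model
#' usemSpec(3, freeA = rbind(c(2, 1), c(3, 2)))  # two same-day paths
#' @export
usemSpec <- function(p, varNames = paste0("V", seq_len(p)),
                     freeA = NULL, freePhi = NULL, freePsi = NULL) {
  new("USEMSpec", p = as.integer(p), varNames = varNames,
      freeA = .indexMatrix(freeA), freePhi = .indexMatrix(freePhi),
      freePsi = .indexMatrix(freePsi))
}

#' SEM fit indices of a fitted uSEM
#'
#' @slot chi2 likelihood-ratio test statistic `(N - 1) * F_ML`.
#' @slot df model degrees of freedom.
#' @slot pChi2 chi-square p-value (1 when `df = 0`).
#' @slot rmsea root mean square error of approximation.
#' @slot srmr standardized root mean square residual.
#' @slot cfi comparative fit index.
#' @slot nnfi non-normed fit index (Tucker--Lewis); 1 by convention
#'   when `df = 0`.
#' @slot nExcellent number of indices meeting the excellent-fit
#'   thresholds (RMSEA <= .05, SRMR <= .05, CFI >= .95, NNFI >= .95).
#' @slot chi2Null,dfNull independence-model baseline.
#' @export
setClass("FitIndices",
  representation(
    chi2 = "numeric", df = "integer", pChi2 = "numeric",
    rmsea = "numeric", srmr = "numeric", cfi = "numeric",
    nnfi = "numeric", nExcellent = "integer",
    chi2Null = "numeric", dfNull = "integer"
  )
)

#' A fitted person-specific hybrid uSEM
#'
#' Maximum-likelihood estimates of the structural matrices together
#' with their standardized versions, per-parameter inference, the
#' sample covariance it was fitted to, and fit indices.
#'
#' @slot spec the [USEMSpec-class] free-parameter pattern.
#' @slot A,Phi,Psi,SigmaXX estimated matrices (`SigmaXX` is the
#'   saturated covariance of the lagged block).
#' @slot standardizedA,standardizedPhi estimates rescaled by
#'   model-implied SDs; `residCor` holds residual correlations.
#' @slot residCor residual correlation matrix from `Psi`.
#' @slot estimates data.frame with one row per free structural
#'   parameter: type, i, j, est, se, z, p.
#' @slot N number of lag-embedded observation rows.
#' @slot S the 2p x 2p sample covariance (lagged block first).
#' @slot fit a [FitIndices-class].
#' @slot converged logical.
#' @slot heywood logical; `TRUE` if a residual variance was bounded at
#'   its lower limit.
#' @seealso [fitUSEM()], [forwardSearch()]
#' @export
setClass("USEMModel",
  representation(
    spec = "USEMSpec",
    A = "matrix", Phi = "matrix", Psi = "matrix", SigmaXX = "matrix",
    standardizedA = "matrix", standardizedPhi = "matrix",
    residCor = "matrix",
    estimates = "data.frame",
    N = "integer",
    S = "matrix",
    fit = "FitIndices",
    converged = "logical",
    heywood = "logical"
  )
)

#' Record of a forward model search
#'
#' @slot steps data.frame with one row per accepted candidate: step,
#'   type, from, to, score, chi2Before, chi2After, rmsea, srmr, cfi,
#'   nnfi, nExcellent.
#' @slot stopReason one of `"fit_excellent"`,
#'   `"no_significant_candidate"`, `"max_steps"`,
#'   `"estimation_failure"`.
#' @export
setClass("SearchTrace",
  representation(steps = "data.frame", stopReason = "character")
)

## ---- regression result classes ----------------------------------------

#' Intraindividual residualized moderated-regression result
#'
#' OLS fit of AR(1)-residualized daily recall on femininity, the
#' binary hormone-milieu phase, and their interaction, for one person.
#'
#' @slot personId participant identifier.
#' @slot coefficients data.frame with rows intercept, femininity,
#'   phase, phase x femininity and columns term, b, SE, t, p.
#' @slot vcov 4 x 4 covariance of the estimates.
#' @slot nUsed number of person-days entering the OLS.
#' @slot arCoef,arN the AR(1) residualization pre-fit: slope and
#'   number of complete day pairs.
#' @slot referenceLevel which phase level (0 or 1) is the reference
#'   (phase = 0 rows), printed with every report.
#' @seealso [fitModeratedModel()], [simpleSlopes()]
#' @export
setClass("ResidRegResult",
  representation(
    personId = "character",
    coefficients = "data.frame",
    vcov = "matrix",
    nUsed = "integer",
    arCoef = "numeric",
    arN = "integer",
    referenceLevel = "character"
  )
)

setValidity("ResidRegResult", function(object) {
  msg <- character()
  cf <- object@coefficients
  if (!all(c("term", "b", "SE", "t", "p") %in% names(cf)))
    msg <- c(msg, "'coefficients' must have columns term, b, SE, t, p")
  else {
    if (any(cf$SE <= 0)) msg <- c(msg, "all SEs must be positive")
    if (any(cf$p < 0 | cf$p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
  }
  V <- object@vcov
  if (!identical(dim(V), c(4L, 4L)) || max(abs(V - t(V))) > 1e-8)
    msg <- c(msg, "'vcov' must be a symmetric 4 x 4 matrix")
  else if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, "'vcov' must be positive semidefinite")
  if (length(msg)) msg else TRUE
})

#' Simple-slopes decomposition of a phase-by-femininity interaction
#'
#' Conditional femininity--recall slopes at each hormone milieu. The
#' identity `slope(low) - slope(high) = b_interaction` holds exactly.
#'
#' @slot slopes data.frame with rows `high_milieu` (phase = 0) and
#'   `low_milieu` (phase = 1) and columns milieu, b, SE, t, p.
#' @slot df residual degrees of freedom used for the t tests.
#' @seealso [simpleSlopes()]
#' @export
setClass("SimpleSlopes",
  representation(slopes = "data.frame", df = "integer")
)
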