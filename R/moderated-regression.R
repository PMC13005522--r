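#' AR(1)-residualize a daily outcome series
#'
#' Accounts for the previous day's value predicting itself: fits
#' `y_t = a + phi * y_{t-1}` by least squares over complete
#' consecutive-day pairs and returns the residuals, which carry the
#' day-to-day variation not explained by yesterday's score. Residuals
#' have mean zero by construction.
#'
#' @param y numeric outcome series on the calendar day grid (`NA` =
#'   missing day).
#' @param day optional day indices (default `1:length(y)`).
#' @return List with `residuals`, `days` (the day index of each
#'   residual), `phi`, `intercept`, `n` (complete pairs used).
#' @export
residualizeAR1 <- function(y, day = seq_along(y)) {
  grid <- rep(NA_real_, max(day))
  grid[day] <- y
  T <- length(grid)
  tNow <- 2:T
  ok <- !is.na(grid[tNow]) & !is.na(grid[tNow - 1L])
  tNow <- tNow[ok]
  if (length(tNow) < 10L)
    stop("insufficient complete pairs: ", length(tNow), " < 10")
  fit <- stats::lm(grid[tNow] ~ grid[tNow - 1L])
  co <- stats::coef(fit)
  list(residuals = unname(stats::residuals(fit)), days = tNow,
       phi = unname(co[2L]), intercept = unname(co[1L]),
       n = length(tNow))
}

#' Fit the intraindividual moderated regression
#'
#' Ordinary least squares of the residualized daily recall on
#' femininity, the binary hormone-milieu phase, and their interaction,
#' with classical SEs and two-sided t tests on `n - 4` degrees of
#' freedom. Phase enters under the convention 1 = low milieu (bleeding
#' or inactive pill); the reference level (phase = 0) is recorded in
#' the result because coefficient signs depend on it.
#'
#' @param r residualized outcome values.
#' @param fem femininity values, day-aligned with `r`.
#' @param phase 0/1 phase values, day-aligned with `r`.
#' @param personId identifier stored in the result.
#' @param referenceLevel label describing the phase = 0 level
#'   (default `"high milieu (phase = 0)"`).
#' @return A [ResidRegResult-class].
#' @export
fitModeratedModel <- function(r, fem, phase, personId = "person",
                              referenceLevel = "high milieu (phase = 0)") {
  if (length(fem) != length(r) || length(phase) != length(r))
    stop("series must be day-aligned")
  keep <- !is.na(r) & !is.na(fem) & !is.na(phase)
  r <- r[keep]; fem <- fem[keep]; phase <- phase[keep]
  if (!all(phase %in% c(0, 1))) stop("'phase' must be 0/1")
  tab <- table(factor(phase, levels = c(0, 1)))
  if (any(tab == 0L)) stop("moderator has no variance")
  if (any(tab < 3L))
    stop("need at least 3 observations at each phase level")
  if (stats::sd(fem) == 0) stop("femininity is constant")
  X <- cbind(1, fem, phase, phase * fem)
  if (kappa(crossprod(X), exact = TRUE) > 1e8)
    stop("collinear design (condition number > 1e8)")
  fit <- stats::lm(r ~ fem + phase + fem:phase)
  sm <- summary(fit)
  cf <- sm$coefficients
  terms <- c("intercept", "femininity", "phase", "phase_x_femininity")
  coefs <- data.frame(term = terms, b = unname(cf[, 1L]),
                      SE = unname(cf[, 2L]), t = unname(cf[, 3L]),
                      p = unname(cf[, 4L]), stringsAsFactors = FALSE)
  V <- unname(stats::vcov(fit))
  dimnames(V) <- list(terms, terms)
  new("ResidRegResult", personId = personId, coefficients = coefs,
      vcov = V, nUsed = length(r),
      arCoef = NA_real_, arN = NA_integer_,
      referenceLevel = referenceLevel)
}

#' Simple-slopes decomposition of the phase interaction
#'
#' Conditional femininity slopes at each hormone milieu: at phase = 0
#' the slope is `b_fem`; at phase = 1 it is `b_fem + b_int` with
#' `SE = sqrt(V_ff + V_ii + 2 V_fi)`. The difference of the two
#' slopes equals the interaction coefficient exactly. t tests use
#' `nUsed - 4` degrees of freedom.
#'
#' @param result a [ResidRegResult-class].
#' @return A [SimpleSlopes-class].
#' @export
simpleSlopes <- function(result) {
  cf <- result@coefficients
  bF <- cf$b[cf$term == "femininity"]
  bI <- cf$b[cf$term == "phase_x_femininity"]
  V <- result@vcov
  seHigh <- sqrt(V["femininity", "femininity"])
  seLow <- sqrt(V["femininity", "femininity"] +
                  V["phase_x_femininity", "phase_x_femininity"] +
                  2 * V["femininity", "phase_x_femininity"])
  df <- result@nUsed - 4L
  slope <- c(bF, bF + bI)
  se <- c(seHigh, seLow)
  tval <- slope / se
  slopes <- data.frame(
    milieu = c("high_milieu", "low_milieu"),
    b = slope, SE = se, t = tval,
    p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    stringsAsFactors = FALSE)
  new("SimpleSlopes", slopes = slopes, df = as.integer(df))
}

#' Run the full moderated-regression workflow for one person
#'
#' Composes [residualizeAR1()] on the outcome, [fitModeratedModel()]
#' on the aligned predictors, and [simpleSlopes()], and reports the
#' phase coding used. Optionally the predictors can also be
#' AR(1)-residualized, and femininity can be mean-centered before the
#' interaction is formed.
#'
#' @param series a [PersonSeries-class] with a recorded phase.
#' @param outcome outcome variable name (default `"recall"`).
#' @param predictor focal predictor name (default `"femininity"`).
#' @param residualizePredictor also residualize the predictor on its
#'   own lag? (default `FALSE`).
#' @param centerPredictor mean-center the predictor? (default
#'   `FALSE`, preserving the reference-level reading of the main
#'   effects).
#' @return List with `result` (a [ResidRegResult-class]), `slopes` (a
#'   [SimpleSlopes-class]) and `report` (character lines noting the
#'   phase coding and options used).
#' @export
runModeratedRegression <- function(series, outcome = "recall",
                                   predictor = "femininity",
                                   residualizePredictor = FALSE,
                                   centerPredictor = FALSE) {
  if (is.null(series@phase)) stop("series has no phase indicator")
  unknown <- setdiff(c(outcome, predictor), colnames(series@values))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  res <- residualizeAR1(series@values[, outcome], day = series@day)
  idx <- match(res$days, series@day)
  fem <- series@values[idx, predictor]
  if (residualizePredictor) {
    fres <- residualizeAR1(series@values[, predictor], day = series@day)
    fem <- rep(NA_real_, length(res$days))
    hit <- match(res$days, fres$days)
    fem[!is.na(hit)] <- fres$residuals[hit[!is.na(hit)]]
  }
  if (centerPredictor) fem <- fem - mean(fem, na.rm = TRUE)
  phase <- series@phase[idx]
  result <- fitModeratedModel(res$residuals, fem, phase,
                              personId = series@personId)
  result@arCoef <- res$phi
  result@arN <- res$n
  report <- c(
    sprintf("person: %s", series@personId),
    "phase coding: 1 = low hormone milieu (bleeding or inactive pill), 0 = high milieu",
    sprintf("reference level: %s", result@referenceLevel),
    sprintf("outcome '%s' residualized on its 1-day lag (phi = %.3f, %d pairs)",
            outcome, res$phi, res$n),
    sprintf("predictor '%s' %s; %s", predictor,
            if (residualizePredictor) "residualized on its 1-day lag"
            else "entered raw",
            if (centerPredictor) "mean-centered" else "not centered"),
    sprintf("n used: %d", result@nUsed))
  list(result = result, slopes = simpleSlopes(result), report = report)
}

#' Coefficient table of a moderated-regression result
#'
#' @param result a [ResidRegResult-class].
#' @return data.frame with columns person_id, term, b, SE, p,
#'   reference_level.
#' @export
coefficientTable <- function(result) {
  cf <- result@coefficients
  data.frame(person_id = result@personId, term = cf$term, b = cf$b,
             SE = cf$SE, p = cf$p,
             reference_level = result@referenceLevel,
             stringsAsFactors = FALSE)
}
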