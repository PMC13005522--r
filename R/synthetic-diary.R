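#' Simulate a daily hormone-milieu phase sequence
#'
#' Generates the per-day binary low/high milieu indicator implied by a
#' regimen: 1 on bleeding days (first `bleedDays` of each natural
#' cycle) or inactive-pill days (last `inactiveDays` of each OC pack),
#' 0 otherwise. Pre-menopause behaves as a natural cycle,
#' post-menopause has no low-milieu days, and perimenopause draws
#' successive cycle lengths uniformly from `periRange` (the only
#' stochastic regimen).
#'
#' @param regimen a [PhaseRegimen-class].
#' @param T number of days.
#' @param seed integer seed (used by the perimenopausal regimen).
#' @return Integer 0/1 vector of length `T`.
#' @examples
#' sum(simulatePhaseSequence(phaseRegimen("natural_cycle"), 28, 1))  # 5
#' sum(simulatePhaseSequence(phaseRegimen("oc_regimen"), 28, 1))     # 7
#' @export
simulatePhaseSequence <- function(regimen, T, seed = 1L) {
  T <- .assertCount(T, "T")
  validObject(regimen)
  kind <- regimen@kind
  if (kind %in% c("natural_cycle", "menopause_pre")) {
    within <- ((seq_len(T) - 1L) %% regimen@cycleLength) + 1L
    return(as.integer(within <= regimen@bleedDays))
  }
  if (kind == "oc_regimen") {
    pack <- regimen@activeDays + regimen@inactiveDays
    within <- ((seq_len(T) - 1L) %% pack) + 1L
    return(as.integer(within > regimen@activeDays))
  }
  if (kind == "menopause_post") return(integer(T))
  if (kind == "menopause_peri") {
    phase <- integer(0)
    withr::with_seed(seed, {
      while (length(phase) < T) {
        len <- sample(seq(regimen@periRange[1L], regimen@periRange[2L]), 1L)
        phase <- c(phase, as.integer(seq_len(len) <= regimen@bleedDays))
      }
    })
    return(phase[seq_len(T)])
  }
  stop("invalid regimen kind: ", kind)
}

#' Simulate a latent structural-VAR (uSEM) series
#'
#' Draws `y_t = (I - A)^-1 (intercepts + Phi y_{t-1} + zeta_t)` with
#' Gaussian innovations `zeta_t ~ N(0, Psi)`, discarding a 50-step
#' burn-in so the returned series is effectively stationary.
#'
#' @param truth a [SimTruth-class]; must be stationary.
#' @param T number of days to return.
#' @param seed integer seed.
#' @param burnin burn-in steps discarded before day 1 (default 50).
#' @return T x p numeric matrix.
#' @export
simulateUSEM <- function(truth, T, seed = 1L, burnin = 50L) {
  T <- .assertCount(T, "T")
  validObject(truth)
  p <- nrow(truth@A)
  B <- solve(diag(p) - truth@A)
  L <- t(chol(truth@Psi))
  total <- T + burnin
  y <- matrix(0, total, p)
  withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(total * p), p, total)
    prev <- numeric(p)
    for (t in seq_len(total)) {
      prev <- as.numeric(B %*% (truth@intercepts + truth@Phi %*% prev +
                                  L %*% eps[, t]))
      y[t, ] <- prev
    }
  })
  y[(burnin + 1L):total, , drop = FALSE]
}

#' Simulate a phase-moderated daily recall series
#'
#' `recall_t = c + ar * recall_{t-1} + (s0 + s1 * phase_t) * fem_t +
#' eps_t` with Gaussian noise; the series starts from the stationary
#' mean `c / (1 - ar)`.
#'
#' @param fem daily femininity series.
#' @param phase daily 0/1 hormone-milieu series, aligned with `fem`.
#' @param s0 femininity slope in the high milieu (phase = 0).
#' @param s1 slope shift in the low milieu (phase = 1).
#' @param ar autoregressive coefficient, `|ar| < 1`.
#' @param noiseSd innovation SD.
#' @param seed integer seed.
#' @param intercept structural intercept `c` (default 0).
#' @return Numeric recall series of the same length.
#' @export
simulateModeratedOutcome <- function(fem, phase, s0, s1, ar, noiseSd,
                                     seed = 1L, intercept = 0) {
  if (length(fem) != length(phase))
    stop("'fem' and 'phase' must be aligned on days")
  if (abs(ar) >= 1) stop("|ar| must be < 1")
  T <- length(fem)
  out <- numeric(T)
  withr::with_seed(seed, {
    eps <- stats::rnorm(T, sd = noiseSd)
    prev <- intercept / (1 - ar)
    for (t in seq_len(T)) {
      prev <- intercept + ar * prev + (s0 + s1 * phase[t]) * fem[t] + eps[t]
      out[t] <- prev
    }
  })
  out
}

#' Map a continuous series onto a bounded Likert scale
#'
#' Affinely maps the series' in-sample 1st--99th percentile range onto
#' `[min, max]`, clips to the bounds, and rounds to the nearest
#' integer for integer-valued scales. A (near-)constant input maps to
#' the scale midpoint.
#'
#' @param values continuous numeric series.
#' @param scale a [ScaleSpec-class].
#' @return Bounded numeric series.
#' @export
discretizeToScale <- function(values, scale) {
  validObject(scale)
  qs <- stats::quantile(values, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
  if (!is.finite(qs[2L] - qs[1L]) || qs[2L] - qs[1L] < 1e-12) {
    out <- rep((scale@min + scale@max) / 2, length(values))
  } else {
    out <- scale@min + (values - qs[1L]) / (qs[2L] - qs[1L]) *
      (scale@max - scale@min)
    out <- pmin(pmax(out, scale@min), scale@max)
  }
  out[is.na(values)] <- NA_real_
  if (scale@integerValued) out <- round(out)
  out
}

#' Apply diary-compliance missingness to a person series
#'
#' Marks each day independently missing (all variables that day, and
#' the phase report) with probability `rate` -- missing completely at
#' random, emulating skipped diary days under the >= 80% compliance
#' standard.
#'
#' @param series a [PersonSeries-class].
#' @param rate whole-day missingness probability in `[0, 0.2]`.
#' @param seed integer seed.
#' @return The masked [PersonSeries-class].
#' @export
applyMissingness <- function(series, rate, seed = 1L) {
  if (rate < 0 || rate > 0.2) stop("'rate' must lie in [0, 0.2]")
  if (rate == 0) return(series)
  T <- length(series@day)
  drop <- withr::with_seed(seed, stats::runif(T) < rate)
  values <- series@values
  values[drop, ] <- NA_real_
  phase <- series@phase
  if (!is.null(phase)) phase[drop] <- NA_integer_
  personSeries(series@personId, values, day = series@day, phase = phase,
               scales = series@scales)
}

#' Simulate a complete synthetic diary study
#'
#' Runs the full generative pipeline for each person: phase sequence
#' from the regimen, latent structural-VAR series from the truth, an
#' optional phase-moderated recall outcome, optional Likert
#' discretization, and whole-day MCAR missingness. Per-person seeds
#' are derived deterministically from `truth@seed`, so an identical
#' configuration reproduces the study exactly.
#'
#' @param config a [SimConfig-class].
#' @return List with `study` (a [DailyStudy-class]) and `truth` (the
#'   generating [SimTruth-class]).
#' @export
simulateStudy <- function(config) {
  validObject(config)
  truth <- config@truth
  T <- config@nDays
  persons <- vector("list", config@nPersons)
  wantRecall <- !is.na(config@recallVariable)
  for (k in seq_len(config@nPersons)) {
    base <- .childSeed(truth@seed, k)
    phase <- simulatePhaseSequence(config@regimen, T, seed = base + 1L)
    latent <- simulateUSEM(truth, T, seed = base + 2L)
    colnames(latent) <- config@varNames
    if (wantRecall) {
      recall <- simulateModeratedOutcome(
        latent[, config@femVariable], phase,
        s0 = truth@slopeBase, s1 = truth@slopePhaseShift,
        ar = truth@recallAR, noiseSd = truth@recallNoiseSD,
        seed = base + 3L)
      latent <- cbind(latent, recall)
      colnames(latent)[ncol(latent)] <- config@recallVariable
    }
    scales <- config@scales[colnames(latent)]
    names(scales) <- colnames(latent)
    if (config@discretize) {
      miss <- vapply(colnames(latent), function(v) is.null(scales[[v]]),
                     logical(1))
      if (any(miss))
        stop("no scale metadata for variable(s): ",
             paste(colnames(latent)[miss], collapse = ", "))
      for (v in colnames(latent))
        latent[, v] <- discretizeToScale(latent[, v], scales[[v]])
      usedScales <- scales
    } else {
      # continuous outputs are unbounded; drop range metadata
      usedScales <- list()
    }
    series <- personSeries(sprintf("sim%02d", k), latent,
                           phase = as.integer(phase), scales = usedScales)
    persons[[k]] <- applyMissingness(series, truth@missingRate,
                                     seed = base + 4L)
  }
  list(study = dailyStudy(persons, studyLength = T), truth = truth)
}

#' Calibrate residual variances for a standardized structural truth
#'
#' Given contemporaneous and lagged coefficient matrices, finds the
#' diagonal residual covariance `Psi` under which the stationary
#' variance of every variable equals 1, so the coefficients can be
#' read as standardized path weights. Solves the stationary Lyapunov
#' relation numerically.
#'
#' @param A,Phi p x p coefficient matrices (stationary).
#' @param seed seed stored in the resulting truth.
#' @param ... passed to [simTruth()].
#' @return A [SimTruth-class] with calibrated diagonal `Psi`.
#' @export
standardizedUSEMTruth <- function(A, Phi, seed = 1L, ...) {
  p <- nrow(A)
  B <- solve(diag(p) - A)
  statVar <- function(psiDiag) {
    Psi <- diag(psiDiag, p)
    M <- B %*% Phi
    Sig <- diag(p)
    # fixed-point iteration of Sigma = M Sigma M' + B Psi B'
    for (i in 1:500) {
      Snew <- M %*% Sig %*% t(M) + B %*% Psi %*% t(B)
      if (max(abs(Snew - Sig)) < 1e-12) { Sig <- Snew; break }
      Sig <- Snew
    }
    diag(Sig)
  }
  obj <- function(logPsi) sum((statVar(exp(logPsi)) - 1)^2)
  opt <- stats::nlminb(rep(0, p), obj)
  if (opt$objective > 1e-8)
    stop("could not calibrate unit stationary variances for this truth")
  simTruth(A = A, Phi = Phi, Psi = diag(exp(opt$par), p), seed = seed, ...)
}

#' Write simulation ground truth as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(
    A = truth@A, Phi = truth@Phi, Psi = truth@Psi,
    intercepts = truth@intercepts,
    slope_base = truth@slopeBase,
    slope_phase_shift = truth@slopePhaseShift,
    recall_ar = truth@recallAR, recall_noise_sd = truth@recallNoiseSD,
    missing_rate = truth@missingRate, seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
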