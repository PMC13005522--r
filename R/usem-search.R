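# Lagrange-multiplier forward search over hybrid-uSEM candidates.

# admissible fixed-at-zero candidates, per the identification rules:
# no contemporaneous self-loops, no reverse of an already-freed
# contemporaneous path, Phi off-diagonals, unordered Psi pairs.
.candidateSet <- function(spec, blocked = NULL) {
  p <- spec@p
  key <- function(type, i, j) paste(type, i, j)
  freeKeys <- character()
  if (nrow(spec@freeA))
    freeKeys <- c(freeKeys,
                  key("contemporaneous", spec@freeA[, 1L], spec@freeA[, 2L]),
                  key("contemporaneous", spec@freeA[, 2L], spec@freeA[, 1L]))
  if (nrow(spec@freePhi))
    freeKeys <- c(freeKeys, key("lagged", spec@freePhi[, 1L],
                                spec@freePhi[, 2L]))
  if (nrow(spec@freePsi))
    freeKeys <- c(freeKeys, key("residual_cov", spec@freePsi[, 1L],
                                spec@freePsi[, 2L]))
  grid <- expand.grid(i = seq_len(p), j = seq_len(p))
  grid <- grid[grid$i != grid$j, ]
  cand <- rbind(
    data.frame(type = "contemporaneous", i = grid$i, j = grid$j),
    data.frame(type = "lagged", i = grid$i, j = grid$j),
    data.frame(type = "residual_cov",
               i = grid$i[grid$i < grid$j], j = grid$j[grid$i < grid$j]))
  keys <- key(cand$type, cand$i, cand$j)
  drop <- keys %in% c(freeKeys, blocked)
  cand <- cand[!drop, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

.addCandidate <- function(spec, type, i, j) {
  if (type == "contemporaneous")
    usemSpec(spec@p, spec@varNames,
             freeA = rbind(spec@freeA, c(i, j)),
             freePhi = spec@freePhi, freePsi = spec@freePsi)
  else if (type == "lagged")
    usemSpec(spec@p, spec@varNames, freeA = spec@freeA,
             freePhi = rbind(spec@freePhi, c(i, j)),
             freePsi = spec@freePsi)
  else
    usemSpec(spec@p, spec@varNames, freeA = spec@freeA,
             freePhi = spec@freePhi,
             freePsi = rbind(spec@freePsi, c(i, j)))
}

.dropParameter <- function(spec, type, i, j) {
  rm1 <- function(m, i, j) {
    hit <- which(m[, 1L] == i & m[, 2L] == j)
    if (length(hit)) m[-hit[1L], , drop = FALSE] else m
  }
  if (type == "contemporaneous")
    usemSpec(spec@p, spec@varNames, freeA = rm1(spec@freeA, i, j),
             freePhi = spec@freePhi, freePsi = spec@freePsi)
  else if (type == "lagged")
    usemSpec(spec@p, spec@varNames, freeA = spec@freeA,
             freePhi = rm1(spec@freePhi, i, j), freePsi = spec@freePsi)
  else
    usemSpec(spec@p, spec@varNames, freeA = spec@freeA,
             freePhi = spec@freePhi, freePsi = rm1(spec@freePsi, i, j))
}

#' Modification indices for all admissible candidates
#'
#' Univariate Lagrange-multiplier (score) statistics estimating the
#' chi-square improvement from freeing each fixed-at-zero candidate
#' parameter without refitting:
#' `MI = (N - 1) g^2 / (2 h)`, where `g` is the gradient of the ML
#' discrepancy with respect to the candidate at the current optimum
#' and `h` its expected-information diagonal adjusted (via the Schur
#' complement) for the model's free parameters. Each MI is
#' asymptotically chi-square with 1 df.
#'
#' @param model a converged [USEMModel-class].
#' @param blocked character keys (`"type i j"`) of candidates to
#'   exclude, as used internally by [forwardSearch()] for reverted
#'   candidates.
#' @return data.frame with columns type, i, j, score, ordered by the
#'   deterministic tie-break (score, then category contemporaneous >
#'   lagged > residual covariance, then row/column order).
#' @export
candidateScores <- function(model, blocked = NULL) {
  spec <- model@spec
  p <- spec@p
  tmpl <- .thetaTemplate(spec)
  cand <- .candidateSet(spec, blocked)
  if (!nrow(cand)) return(cbind(cand, score = numeric(0)))
  S <- model@S
  ix <- seq_len(p); iy <- p + seq_len(p)
  Sxx <- S[ix, ix]; Syx <- S[iy, ix]; Syy <- S[iy, iy]
  theta <- model@estimates$est
  st <- .usemState(theta, tmpl, p, Sxx, Syx, Syy)
  gm <- .gradientMatrices(st, Sxx, Syx)
  gCand <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand$i[k]; j <- cand$j[k]
    switch(cand$type[k],
      contemporaneous = gm$GA[i, j],
      lagged = gm$GPhi[i, j],
      residual_cov = 2 * gm$KB[i, j])
  }, numeric(1))
  all <- rbind(tmpl[, c("type", "i", "j")], cand)
  H <- .expectedInfo(all, st, Sxx, p)
  q <- nrow(tmpl)
  Hff <- H[seq_len(q), seq_len(q), drop = FALSE]
  HffInv <- tryCatch(solve(Hff), error = function(e) NULL)
  score <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    c0 <- q + k
    hEff <- H[c0, c0]
    if (!is.null(HffInv) && q > 0L) {
      v <- H[seq_len(q), c0]
      hEff <- hEff - drop(crossprod(v, HffInv %*% v))
    }
    score[k] <- if (hEff > 1e-10)
      (model@N - 1) * gCand[k]^2 / (2 * hEff) else 0
  }
  out <- cbind(cand, score = score)
  typeRank <- match(out$type, c("contemporaneous", "lagged", "residual_cov"))
  out[order(-out$score, typeRank, out$i, out$j), , drop = FALSE]
}

#' Forward Lagrange-multiplier search for a person-specific network
#'
#' Starts from the null structural model (autoregressions and
#' residual variances only, exogenous block saturated) and iteratively
#' frees the candidate with the largest significant modification
#' index, refitting after each addition, until the fit is excellent on
#' at least `nExcellentStop` of the four indices, no candidate exceeds
#' the chi-square(1) critical value at `alpha`, or `maxSteps` is
#' reached. A step whose refit fails to converge (or drives `I - A`
#' near singularity) is reverted and that candidate blocked.
#' Non-significant freed parameters are pruned afterwards by default
#' (autoregressions exempt); pruning is a convention of the estimation
#' framework, flagged in every exported report.
#'
#' @param data N x 2p lag-embedded matrix, z-scored per column, lagged
#'   block first (see [lagEmbed()] and [standardizeColumns()]).
#' @param N number of rows (default `nrow(data)`).
#' @param varNames endogenous variable names (default from columns).
#' @param alpha candidate significance level on chi-square(1)
#'   (default .05). With the default `correction = "bonferroni"` the
#'   level is family-wise over the candidate set scanned at each step,
#'   which keeps the false-discovery behaviour of the whole search
#'   near `alpha`; `correction = "none"` tests each candidate at
#'   `alpha` individually.
#' @param correction multiplicity handling for the candidate test.
#' @param maxSteps maximum accepted additions (default `p * 2p`).
#' @param prune prune non-significant paths afterwards? (default
#'   `TRUE`).
#' @param nExcellentStop stop once this many indices are excellent
#'   (default 2 of 4).
#' @param thresholds excellent-fit cutoffs, see [computeFitIndices()].
#' @return List with `model` (a [USEMModel-class]) and `trace` (a
#'   [SearchTrace-class]).
#' @export
forwardSearch <- function(data, N = nrow(data),
                          varNames = NULL, alpha = 0.05,
                          correction = c("bonferroni", "none"),
                          maxSteps = NULL, prune = TRUE,
                          nExcellentStop = 2L,
                          thresholds = c(rmsea = 0.05, srmr = 0.05,
                                         cfi = 0.95, nnfi = 0.95)) {
  correction <- match.arg(correction)
  p <- ncol(data) / 2L
  if (p != round(p)) stop("'data' must have 2p columns")
  p <- as.integer(p)
  if (is.null(varNames)) {
    varNames <- colnames(data)[p + seq_len(p)] %||% paste0("V", seq_len(p))
  }
  if (N < 10L * p)
    warning("N = ", N, " is small for p = ", p,
            "; at least 10p rows are recommended")
  maxSteps <- maxSteps %||% (p * 2L * p)
  S <- stats::cov(data)

  spec <- usemSpec(p, varNames)
  model <- fitUSEM(spec, S, N)
  steps <- list()
  blocked <- character()
  stopReason <- "max_steps"
  nAccepted <- 0L

  repeat {
    fit <- model@fit
    if (fit@nExcellent >= nExcellentStop) { stopReason <- "fit_excellent"; break }
    if (nAccepted >= maxSteps) { stopReason <- "max_steps"; break }
    scores <- candidateScores(model, blocked)
    level <- if (correction == "bonferroni")
      alpha / max(nrow(scores), 1L) else alpha
    crit <- stats::qchisq(1 - level, df = 1L)
    scores <- scores[scores$score > crit, , drop = FALSE]
    hadSignificant <- nrow(scores) > 0L
    accepted <- FALSE
    while (nrow(scores)) {
      top <- scores[1L, ]
      newSpec <- .addCandidate(spec, top$type, top$i, top$j)
      trial <- tryCatch(fitUSEM(newSpec, S, N,
                                start = .carryStart(model, newSpec)),
                        error = function(e) NULL)
      bad <- is.null(trial) || !trial@converged ||
        kappa(diag(p) - trial@A, exact = TRUE) > 1e10
      if (bad) {
        blocked <- c(blocked, paste(top$type, top$i, top$j))
        scores <- scores[-1L, , drop = FALSE]
        next
      }
      nAccepted <- nAccepted + 1L
      steps[[nAccepted]] <- data.frame(
        step = nAccepted, type = top$type,
        from = varNames[top$j], to = varNames[top$i],
        score = top$score, chi2Before = model@fit@chi2,
        chi2After = trial@fit@chi2, rmsea = trial@fit@rmsea,
        srmr = trial@fit@srmr, cfi = trial@fit@cfi,
        nnfi = trial@fit@nnfi, nExcellent = trial@fit@nExcellent,
        stringsAsFactors = FALSE)
      spec <- newSpec
      model <- trial
      accepted <- TRUE
      break
    }
    if (!accepted) {
      stopReason <- if (hadSignificant) "estimation_failure"
        else "no_significant_candidate"
      break
    }
  }

  if (prune) model <- pruneNonsignificant(model, alpha = alpha)
  trace <- new("SearchTrace",
               steps = if (length(steps)) do.call(rbind, steps) else
                 data.frame(step = integer(), type = character(),
                            from = character(), to = character(),
                            score = numeric(), chi2Before = numeric(),
                            chi2After = numeric(), rmsea = numeric(),
                            srmr = numeric(), cfi = numeric(),
                            nnfi = numeric(), nExcellent = integer(),
                            stringsAsFactors = FALSE),
               stopReason = stopReason)
  list(model = model, trace = trace)
}

# warm start for a spec that extends (or shrinks) a fitted model
.carryStart <- function(model, newSpec) {
  tmpl <- .thetaTemplate(newSpec)
  old <- model@estimates
  key <- function(d) paste(d$type, d$i, d$j)
  start <- numeric(nrow(tmpl))
  hit <- match(key(tmpl), key(old))
  start[!is.na(hit)] <- old$est[hit[!is.na(hit)]]
  start[tmpl$type == "residual_var" & is.na(hit)] <- 0.5
  start
}

#' Prune non-significant structural parameters
#'
#' Iteratively removes the least-significant freed structural
#' parameter with `p > alpha` and refits, until all remaining freed
#' parameters are significant. Autoregressions (lagged diagonal) and
#' residual variances are exempt.
#'
#' @param model a converged [USEMModel-class].
#' @param alpha significance level (default .05).
#' @return The pruned [USEMModel-class] (possibly unchanged).
#' @export
pruneNonsignificant <- function(model, alpha = 0.05) {
  repeat {
    est <- model@estimates
    eligible <- (est$type == "contemporaneous") |
      (est$type == "lagged" & est$i != est$j) |
      (est$type == "residual_cov")
    drop <- which(eligible & est$p > alpha)
    if (!length(drop)) return(model)
    worst <- drop[which.max(est$p[drop])]
    spec <- .dropParameter(model@spec, est$type[worst], est$i[worst],
                           est$j[worst])
    refit <- tryCatch(fitUSEM(spec, model@S, model@N,
                              start = .carryStart(model, spec)),
                      error = function(e) NULL)
    if (is.null(refit)) return(model)
    model <- refit
  }
}

#' Standardized path matrices of a fitted uSEM
#'
#' Estimates rescaled by the model-implied SDs of the endogenous
#' variables (and the sample SDs of the lagged block), plus residual
#' correlations. When the inputs were z-scored the rescaling is a
#' near-identity exactness correction.
#'
#' @param model a [USEMModel-class].
#' @return List with `A`, `Phi` (standardized) and `residCor`.
#' @export
standardizedPaths <- function(model) {
  list(A = model@standardizedA, Phi = model@standardizedPhi,
       residCor = model@residCor)
}

#' Edge list of a fitted person-specific network
#'
#' One row per freed structural parameter: directed contemporaneous
#' (same-day) paths, directed lagged (next-day) paths including the
#' autoregressions, and unordered residual covariances (canonical
#' from/to order). Weights are standardized (residual covariances as
#' correlations); SEs and p-values refer to the unstandardized
#' estimates.
#'
#' @param model a [USEMModel-class].
#' @return data.frame with columns from, to, type, weight, se, p.
#' @export
networkEdges <- function(model) {
  est <- model@estimates
  est <- est[est$type != "residual_var", , drop = FALSE]
  vn <- model@spec@varNames
  weight <- vapply(seq_len(nrow(est)), function(k) {
    i <- est$i[k]; j <- est$j[k]
    switch(est$type[k],
      contemporaneous = model@standardizedA[i, j],
      lagged = model@standardizedPhi[i, j],
      residual_cov = model@residCor[i, j])
  }, numeric(1))
  from <- est$from; to <- est$to
  isCov <- est$type == "residual_cov"
  from[isCov] <- vn[pmin(est$i[isCov], est$j[isCov])]
  to[isCov] <- vn[pmax(est$i[isCov], est$j[isCov])]
  out <- data.frame(from = from, to = to, type = est$type,
                    weight = weight, se = est$se, p = est$p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export a fitted network to CSV and JSON
#'
#' Writes the [networkEdges()] table as CSV and, alongside it, a JSON
#' report with the fit indices, the search trace (if given), the
#' chi-square multiplier convention, and whether pruning was applied.
#'
#' @param model a [USEMModel-class].
#' @param path output CSV path.
#' @param trace optional [SearchTrace-class] to embed in the report.
#' @param jsonPath report path (default `<path>.json`).
#' @param pruned logical recorded in the report (default `TRUE`, the
#'   search default).
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(model, path, trace = NULL,
                          jsonPath = paste0(path, ".json"),
                          pruned = TRUE) {
  edges <- networkEdges(model)
  num <- vapply(edges, is.numeric, logical(1))
  edges[num] <- lapply(edges[num], .formatNumeric)
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  fit <- model@fit
  report <- list(
    fit = list(chi2 = fit@chi2, df = fit@df, p = fit@pChi2,
               rmsea = fit@rmsea, srmr = fit@srmr, cfi = fit@cfi,
               nnfi = fit@nnfi, n_excellent = fit@nExcellent),
    N = model@N,
    chi2_multiplier = "N-1",
    pruned = pruned,
    pruning_note = "pruning of non-significant paths is an estimation-framework convention (autoregressions exempt)",
    converged = model@converged,
    heywood = model@heywood)
  if (!is.null(trace))
    report$trace <- list(stop_reason = trace@stopReason,
                         steps = trace@steps)
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
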