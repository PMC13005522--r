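# ML machinery for the hybrid uSEM on the lag-embedded covariance.
#
# Data layout: 2p columns, lagged (exogenous) block x first, current
# (endogenous) block y second. Structural model y = A y + Phi x + zeta,
# zeta ~ N(0, Psi), with the covariance of x saturated. Because the
# likelihood factorizes as f(x, y) = f(x) f(y | x), the ML estimate of
# Sigma_xx is S_xx and the structural parameters maximize the
# conditional likelihood; the ML discrepancy decomposes additively, so
# the expected information is block-diagonal between the Sigma_xx
# block and the structural block. All fitting, score tests and SEs
# therefore operate on the structural block only, which is exact.

# one row per free structural parameter, in a fixed order
.thetaTemplate <- function(spec) {
  p <- spec@p
  tm <- list()
  if (nrow(spec@freeA))
    tm[[length(tm) + 1L]] <- data.frame(type = "contemporaneous",
                                        i = spec@freeA[, 1L],
                                        j = spec@freeA[, 2L])
  tm[[length(tm) + 1L]] <- data.frame(type = "lagged", i = seq_len(p),
                                      j = seq_len(p))
  if (nrow(spec@freePhi))
    tm[[length(tm) + 1L]] <- data.frame(type = "lagged",
                                        i = spec@freePhi[, 1L],
                                        j = spec@freePhi[, 2L])
  tm[[length(tm) + 1L]] <- data.frame(type = "residual_var",
                                      i = seq_len(p), j = seq_len(p))
  if (nrow(spec@freePsi))
    tm[[length(tm) + 1L]] <- data.frame(type = "residual_cov",
                                        i = spec@freePsi[, 1L],
                                        j = spec@freePsi[, 2L])
  do.call(rbind, tm)
}

.thetaToMatrices <- function(theta, tmpl, p) {
  A <- matrix(0, p, p); Phi <- matrix(0, p, p); Psi <- matrix(0, p, p)
  for (k in seq_len(nrow(tmpl))) {
    i <- tmpl$i[k]; j <- tmpl$j[k]; v <- theta[k]
    switch(tmpl$type[k],
      contemporaneous = A[i, j] <- v,
      lagged = Phi[i, j] <- v,
      residual_var = Psi[i, i] <- v,
      residual_cov = { Psi[i, j] <- v; Psi[j, i] <- v })
  }
  list(A = A, Phi = Phi, Psi = Psi)
}

# shared pieces of the conditional discrepancy at theta
.usemState <- function(theta, tmpl, p, Sxx, Syx, Syy) {
  m <- .thetaToMatrices(theta, tmpl, p)
  IA <- diag(p) - m$A
  B <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  Pi <- B %*% m$Phi
  Omega <- B %*% m$Psi %*% t(B)
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Oi <- chol2inv(ch)
  M <- Syy - Pi %*% t(Syx) - Syx %*% t(Pi) + Pi %*% Sxx %*% t(Pi)
  list(A = m$A, Phi = m$Phi, Psi = m$Psi, B = B, Pi = Pi, Omega = Omega,
       Oi = Oi, M = M, ldetO = 2 * sum(log(diag(ch))))
}

.usemF <- function(theta, tmpl, p, Sxx, Syx, Syy, ldetSygx) {
  st <- .usemState(theta, tmpl, p, Sxx, Syx, Syy)
  if (is.null(st)) return(1e10)
  st$ldetO + sum(st$Oi * st$M) - ldetSygx - p
}

.usemGradient <- function(theta, tmpl, p, Sxx, Syx, Syy, ldetSygx) {
  st <- .usemState(theta, tmpl, p, Sxx, Syx, Syy)
  if (is.null(st)) return(rep(0, length(theta)))
  gm <- .gradientMatrices(st, Sxx, Syx)
  g <- numeric(nrow(tmpl))
  for (k in seq_len(nrow(tmpl))) {
    i <- tmpl$i[k]; j <- tmpl$j[k]
    g[k] <- switch(tmpl$type[k],
      contemporaneous = gm$GA[i, j],
      lagged = gm$GPhi[i, j],
      residual_var = gm$KB[i, i],
      residual_cov = 2 * gm$KB[i, j])
  }
  g
}

# dF/dA, dF/dPhi (full matrices) and the Psi kernel KB = B' K B
.gradientMatrices <- function(st, Sxx, Syx) {
  GPi <- 2 * st$Oi %*% (st$Pi %*% Sxx - Syx)
  K <- st$Oi - st$Oi %*% st$M %*% st$Oi
  KB <- t(st$B) %*% K %*% st$B
  GA <- 2 * t(st$Omega %*% K %*% st$B) + t(st$B) %*% GPi %*% t(st$Pi)
  GPhi <- t(st$B) %*% GPi
  list(GA = GA, GPhi = GPhi, KB = KB)
}

# full 2p x 2p implied covariance and per-parameter derivatives
.impliedSigma <- function(st, Sxx) {
  W <- st$Phi %*% Sxx %*% t(st$Phi) + st$Psi
  Syy <- st$B %*% W %*% t(st$B)
  Syx <- st$B %*% st$Phi %*% Sxx
  rbind(cbind(Sxx, t(Syx)), cbind(Syx, Syy))
}

.sigmaDeriv <- function(type, i, j, st, Sxx, p) {
  E <- function(a, b) { m <- matrix(0, p, p); m[a, b] <- 1; m }
  W <- st$Phi %*% Sxx %*% t(st$Phi) + st$Psi
  zero <- matrix(0, p, p)
  if (type == "contemporaneous") {
    dB <- st$B %*% E(i, j) %*% st$B
    dYY <- dB %*% W %*% t(st$B); dYY <- dYY + t(dYY)
    dYX <- dB %*% st$Phi %*% Sxx
  } else if (type == "lagged") {
    U <- E(i, j) %*% Sxx %*% t(st$Phi)
    dYY <- st$B %*% (U + t(U)) %*% t(st$B)
    dYX <- st$B %*% E(i, j) %*% Sxx
  } else if (type == "residual_var") {
    dYY <- st$B %*% E(i, i) %*% t(st$B)
    dYX <- zero
  } else {
    dYY <- st$B %*% (E(i, j) + E(j, i)) %*% t(st$B)
    dYX <- zero
  }
  rbind(cbind(zero, t(dYX)), cbind(dYX, dYY))
}

# expected information (Hessian of F at S = Sigma) over a parameter set
.expectedInfo <- function(params, st, Sxx, p) {
  Sigma <- .impliedSigma(st, Sxx)
  Sinv <- solve(Sigma)
  Pmats <- lapply(seq_len(nrow(params)), function(k)
    Sinv %*% .sigmaDeriv(params$type[k], params$i[k], params$j[k],
                         st, Sxx, p))
  q <- length(Pmats)
  H <- matrix(0, q, q)
  for (a in seq_len(q)) {
    Pa <- Pmats[[a]]
    for (b in a:q) {
      H[a, b] <- sum(Pa * t(Pmats[[b]]))
      H[b, a] <- H[a, b]
    }
  }
  H
}

#' Model-implied covariance of a fitted uSEM
#'
#' Assembles the 2p x 2p covariance implied by the estimates: with
#' `B = (I - A)^-1`, the endogenous block is
#' `B (Phi Sigma_xx Phi' + Psi) B'`, the cross block `B Phi Sigma_xx`,
#' and the exogenous block `Sigma_xx` itself (lagged block first).
#'
#' @param model a [USEMModel-class].
#' @return Symmetric 2p x 2p matrix.
#' @export
impliedCovariance <- function(model) {
  p <- model@spec@p
  B <- solve(diag(p) - model@A)
  st <- list(B = B, Phi = model@Phi, Psi = model@Psi)
  Sigma <- .impliedSigma(st, model@SigmaXX)
  nm <- c(paste0(model@spec@varNames, "_lag"), model@spec@varNames)
  dimnames(Sigma) <- list(nm, nm)
  Sigma
}

#' Fit a hybrid uSEM by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - 2p` over the free
#' structural parameters of `spec`. The saturated exogenous block is
#' concentrated out exactly (its ML estimate is the sample `S_xx`).
#' Optimization runs quasi-Newton with analytic gradients followed by
#' Fisher-scoring polish; convergence requires a gradient norm below
#' `1e-6`. `chi2 = (N - 1) * F` at the optimum; SEs come from the
#' inverse expected information. Residual variances are bounded below
#' at `1e-6`; a fit ending on that bound is flagged as a Heywood case.
#'
#' @param spec a [USEMSpec-class].
#' @param S 2p x 2p sample covariance, lagged block first (e.g.
#'   `cov()` of a [lagEmbed()] matrix).
#' @param N number of observation rows behind `S`.
#' @param start optional start values for the structural parameters.
#' @return A [USEMModel-class].
#' @export
fitUSEM <- function(spec, S, N, start = NULL) {
  validObject(spec)
  p <- spec@p
  if (!identical(dim(S), c(2L * p, 2L * p)))
    stop("'S' must be 2p x 2p")
  if (inherits(try(chol(S), silent = TRUE), "try-error"))
    stop("'S' must be positive definite")
  tmpl <- .thetaTemplate(spec)
  qTotal <- nrow(tmpl) + p * (p + 1L) / 2L
  if (N <= qTotal)
    stop("N must exceed the number of free parameters (", qTotal, ")")
  ix <- seq_len(p); iy <- p + seq_len(p)
  Sxx <- S[ix, ix, drop = FALSE]
  Syx <- S[iy, ix, drop = FALSE]
  Syy <- S[iy, iy, drop = FALSE]
  Sygx <- Syy - Syx %*% solve(Sxx, t(Syx))
  ldetSygx <- determinant(Sygx)$modulus[1L]

  if (is.null(start)) {
    start <- numeric(nrow(tmpl))
    condVar <- diag(Sygx)
    start[tmpl$type == "residual_var"] <- pmax(condVar, 0.05)
  }
  lower <- rep(-Inf, nrow(tmpl))
  lower[tmpl$type == "residual_var"] <- 1e-6

  fn <- function(th) .usemF(th, tmpl, p, Sxx, Syx, Syy, ldetSygx)
  gr <- function(th) .usemGradient(th, tmpl, p, Sxx, Syx, Syy, ldetSygx)
  opt <- stats::nlminb(start, fn, gr, lower = lower,
                       control = list(iter.max = 500L, eval.max = 1000L,
                                      rel.tol = 1e-12))
  theta <- opt$par

  # Fisher-scoring polish: Newton steps on the expected information
  # tighten the optimum well past nlminb's stopping point, which the
  # saturation identity (chi2 = 0 at df = 0) and the per-equation OLS
  # equivalence rely on.
  for (iter in 1:50) {
    g <- gr(theta)
    if (max(abs(g)) < 1e-8) break
    st <- .usemState(theta, tmpl, p, Sxx, Syx, Syy)
    if (is.null(st)) break
    H <- .expectedInfo(tmpl, st, Sxx, p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- fn(theta)
    ok <- FALSE
    for (h in c(1, 0.5, 0.25, 0.1, 0.01)) {
      cand <- pmax(theta - h * step, lower)
      if (fn(cand) <= f0 + 1e-12) { theta <- cand; ok <- TRUE; break }
    }
    if (!ok) break
  }

  g <- gr(theta)
  converged <- max(abs(g)) < 1e-6
  heywood <- any(tmpl$type == "residual_var" & theta <= 1e-6 + 1e-12)
  st <- .usemState(theta, tmpl, p, Sxx, Syx, Syy)
  if (is.null(st)) stop("estimation_failure: implied covariance not PD")
  Fval <- fn(theta)
  chi2 <- max((N - 1) * Fval, 0)
  totalMoments <- (2L * p) * (2L * p + 1L) / 2L
  df <- as.integer(totalMoments - qTotal)

  H <- .expectedInfo(tmpl, st, Sxx, p)
  covTheta <- tryCatch(2 / (N - 1) * solve(H), error = function(e)
    matrix(NA_real_, nrow(tmpl), nrow(tmpl)))
  se <- sqrt(pmax(diag(covTheta), 0))
  z <- theta / se
  est <- data.frame(
    type = tmpl$type, i = tmpl$i, j = tmpl$j,
    from = spec@varNames[tmpl$j], to = spec@varNames[tmpl$i],
    est = theta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)

  Sigma <- .impliedSigma(st, Sxx)
  fit <- computeFitIndices(chi2, df, N, S, Sigma)

  sdY <- sqrt(diag(Sigma[iy, iy, drop = FALSE]))
  sdX <- sqrt(diag(Sxx))
  stdA <- st$A * outer(1 / sdY, sdY)
  stdPhi <- st$Phi * outer(1 / sdY, sdX)
  residCor <- stats::cov2cor(st$Psi)
  dn <- list(spec@varNames, spec@varNames)
  dimnames(stdA) <- dn; dimnames(stdPhi) <- dn; dimnames(residCor) <- dn
  A <- st$A; Phi <- st$Phi; Psi <- st$Psi
  dimnames(A) <- dn; dimnames(Phi) <- dn; dimnames(Psi) <- dn

  new("USEMModel", spec = spec, A = A, Phi = Phi, Psi = Psi,
      SigmaXX = Sxx, standardizedA = stdA, standardizedPhi = stdPhi,
      residCor = residCor, estimates = est, N = as.integer(N), S = S,
      fit = fit, converged = converged, heywood = heywood)
}

#' SEM fit indices from a chi-square and its baseline
#'
#' Computes RMSEA, SRMR, CFI and NNFI (Tucker--Lewis) for a fitted
#' covariance-structure model, with the independence model (all
#' covariances zero, variances free) as the baseline computed from
#' `S`. Conventions: `rmsea = sqrt(max(chi2 - df, 0) / (df (N - 1)))`
#' and 0 when `df = 0`; SRMR averages squared standardized residual
#' covariances over the unique `i <= j` moments; NNFI is reported as 1
#' when `df = 0`. `nExcellent` counts indices meeting RMSEA <= .05,
#' SRMR <= .05, CFI >= .95, NNFI >= .95.
#'
#' @param chi2 model chi-square (`(N - 1) * F`).
#' @param df model degrees of freedom.
#' @param N sample size behind the covariance.
#' @param S sample covariance matrix.
#' @param Sigma model-implied covariance; when `NULL`, SRMR is `NA`.
#' @param thresholds named numeric vector of excellent-fit cutoffs
#'   (`rmsea`, `srmr`, `cfi`, `nnfi`).
#' @return A [FitIndices-class].
#' @export
computeFitIndices <- function(chi2, df, N, S, Sigma = NULL,
                              thresholds = c(rmsea = 0.05, srmr = 0.05,
                                             cfi = 0.95, nnfi = 0.95)) {
  df <- as.integer(df)
  k <- nrow(S)
  ldetS <- determinant(S)$modulus[1L]
  chi2Null <- (N - 1) * (sum(log(diag(S))) - ldetS)
  dfNull <- as.integer(k * (k - 1L) / 2L)

  rmsea <- if (df == 0L) 0 else sqrt(max(chi2 - df, 0) / (df * (N - 1)))
  srmr <- NA_real_
  if (!is.null(Sigma)) {
    d <- sqrt(diag(S))
    res <- (S - Sigma) / outer(d, d)
    srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  }
  denom <- max(chi2Null - dfNull, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  if (df == 0L) {
    nnfi <- 1
  } else {
    ratioNull <- chi2Null / dfNull
    nnfi <- (ratioNull - chi2 / df) / (ratioNull - 1)
  }
  pChi2 <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  nExcellent <- sum(c(rmsea <= thresholds["rmsea"],
                      isTRUE(srmr <= thresholds["srmr"]),
                      cfi >= thresholds["cfi"],
                      nnfi >= thresholds["nnfi"]), na.rm = TRUE)
  new("FitIndices", chi2 = chi2, df = df, pChi2 = pChi2, rmsea = rmsea,
      srmr = srmr, cfi = cfi, nnfi = nnfi,
      nExcellent = as.integer(nExcellent),
      chi2Null = chi2Null, dfNull = dfNull)
}
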