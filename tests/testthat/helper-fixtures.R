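# Shared fixture builders: everything is generated in code.

srisScales <- function() {
  list(femininity = scaleSpec("femininity", 1, 5),
       masculinity = scaleSpec("masculinity", 1, 5))
}

# tiny two-person diary CSV on disk; returns the path
writeToyDiary <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "person_id,day,femininity,masculinity",
    "p1,1,3,4",
    "p1,2,4,",
    "p1,3,5,2",
    "p2,1,2,2",
    "p2,2,2,3",
    "p2,3,3,3"), path)
  path
}

# continuous PersonSeries with optional missing days
makeSeries <- function(values, personId = "p1", phase = NULL,
                       scales = list()) {
  personSeries(personId, as.matrix(values), phase = phase,
               scales = scales)
}

# Heterogeneous autoregressions (diary variables differ in day-to-day
# inertia; AR asymmetry is also what identifies the direction of
# contemporaneous paths in a structural VAR).
diaryAR <- c(0.5, 0.25, 0.45, 0.2)

# 4-variable truth with autoregressions only, unit stationary variances
nullTruth <- function(seed = 1L, ...) {
  standardizedUSEMTruth(matrix(0, 4, 4), diag(diaryAR), seed = seed, ...)
}

# truth with three structural paths of standardized weight 0.4:
# two contemporaneous (V1 -> V2, V3 -> V4) and one lagged (V2 -> V3)
threePathTruth <- function(seed = 1L, ...) {
  A <- matrix(0, 4, 4)
  A[2, 1] <- 0.4
  A[4, 3] <- 0.4
  Phi <- diag(diaryAR)
  Phi[3, 2] <- 0.4
  standardizedUSEMTruth(A, Phi, seed = seed, ...)
}

# z-scored lag-embedded matrix from a simulated continuous series
simEmbed <- function(truth, T, seed) {
  y <- simulateUSEM(truth, T, seed = seed)
  colnames(y) <- paste0("V", seq_len(ncol(y)))
  emb <- cbind(y[-T, , drop = FALSE], y[-1, , drop = FALSE])
  colnames(emb) <- c(paste0(colnames(y), "_lag"), colnames(y))
  list(data = standardizeColumns(emb)$scaled, N = T - 1L,
       varNames = colnames(y))
}
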