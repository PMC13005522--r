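test_that("modification indices track brute-force refit improvements", {
  tr <- threePathTruth(seed = 11L)
  emb <- simEmbed(tr, 200, seed = 11L)
  S <- cov(emb$data); N <- emb$N
  m0 <- fitUSEM(usemSpec(4, emb$varNames), S, N)
  sc <- candidateScores(m0)
  # already-free parameters are absent from the candidate map
  expect_false(any(sc$type == "lagged" & sc$i == sc$j))
  dchi <- vapply(seq_len(nrow(sc)), function(k) {
    sp <- idiodyn:::.addCandidate(m0@spec, sc$type[k], sc$i[k], sc$j[k])
    m0@fit@chi2 - fitUSEM(sp, S, N)@fit@chi2
  }, numeric(1))
  expect_gte(cor(sc$score, dchi, method = "spearman"), 0.9)
  # candidate count: 12 contemporaneous + 12 lagged + 6 residual pairs
  expect_identical(nrow(sc), 30L)
})

test_that("the true omitted path earns the top modification index", {
  # omitted lagged path: direction is well identified, exact top hit
  hitsLag <- 0L
  nRep <- 25L
  for (k in seq_len(nRep)) {
    Phi <- diag(diaryAR); Phi[3, 1] <- 0.4
    tr <- standardizedUSEMTruth(matrix(0, 4, 4), Phi, seed = k)
    emb <- simEmbed(tr, 100, seed = 100 + k)
    m0 <- fitUSEM(usemSpec(4, emb$varNames), cov(emb$data), emb$N)
    top <- candidateScores(m0)[1, ]
    if (top$type == "lagged" && top$i == 3 && top$j == 1)
      hitsLag <- hitsLag + 1L
  }
  expect_gte(hitsLag / nRep, 0.8)

  # omitted contemporaneous path: the flagged dependence involves the
  # right variable pair (direction is only weakly identified at T=100)
  hitsPair <- 0L
  for (k in seq_len(nRep)) {
    A <- matrix(0, 4, 4); A[3, 1] <- 0.4
    tr <- standardizedUSEMTruth(A, diag(diaryAR), seed = k)
    emb <- simEmbed(tr, 100, seed = 200 + k)
    m0 <- fitUSEM(usemSpec(4, emb$varNames), cov(emb$data), emb$N)
    top <- candidateScores(m0)[1, ]
    if (all(sort(c(top$i, top$j)) == c(1L, 3L)))
      hitsPair <- hitsPair + 1L
  }
  expect_gte(hitsPair / nRep, 0.8)
})

test_that("modification indices of a null candidate are chi-square(1) calibrated", {
  tr <- nullTruth(seed = 13L)
  mi <- vapply(1:500, function(k) {
    emb <- simEmbed(tr, 200, seed = 2000 + k)
    m0 <- fitUSEM(usemSpec(4, emb$varNames), cov(emb$data), emb$N)
    sc <- candidateScores(m0)
    sc$score[sc$type == "contemporaneous" & sc$i == 2 & sc$j == 1]
  }, numeric(1))
  q95 <- unname(quantile(mi, 0.95))
  expect_gte(q95, 2.8)
  expect_lte(q95, 5.0)
})

test_that("forward search recovers planted structure and stays quiet under the null", {
  # average recovery across a few draws with three true paths
  tr <- threePathTruth(seed = 14L)
  found <- numeric(10)
  for (k in 1:10) {
    emb <- simEmbed(tr, 100, seed = 400 + k)
    res <- forwardSearch(emb$data, N = emb$N, varNames = emb$varNames)
    edges <- networkEdges(res$model)
    hasEdge <- function(type, from, to)
      any(edges$type == type & edges$from == from & edges$to == to)
    found[k] <- hasEdge("contemporaneous", "V1", "V2") +
      hasEdge("contemporaneous", "V3", "V4") +
      hasEdge("lagged", "V2", "V3")
    # chi2 non-increasing over accepted steps
    expect_true(all(diff(res$trace@steps$chi2After) <= 1e-8) ||
                  nrow(res$trace@steps) <= 1L)
    expect_true(all(res$trace@steps$chi2After <=
                      res$trace@steps$chi2Before + 1e-8))
  }
  expect_gte(mean(found), 2)

  # under the null truth the search usually adds nothing
  quiet <- 0L
  for (k in 1:10) {
    embN <- simEmbed(nullTruth(seed = 15L), 100, seed = 300 + k)
    rN <- forwardSearch(embN$data, N = embN$N, varNames = embN$varNames)
    extra <- networkEdges(rN$model)
    extra <- extra[!(extra$type == "lagged" & extra$from == extra$to), ]
    if (nrow(extra) == 0L) quiet <- quiet + 1L
  }
  expect_gte(quiet, 7L)
})

test_that("pruning removes only non-significant non-autoregressive paths", {
  tr <- nullTruth(seed = 16L)
  emb <- simEmbed(tr, 150, seed = 16L)
  S <- cov(emb$data); N <- emb$N
  # force a spurious contemporaneous path into the model
  forced <- fitUSEM(usemSpec(4, emb$varNames, freeA = rbind(c(2, 1))), S, N)
  pSpur <- forced@estimates$p[forced@estimates$type == "contemporaneous"]
  pruned <- pruneNonsignificant(forced)
  if (pSpur > 0.05) {
    expect_identical(nrow(pruned@spec@freeA), 0L)
  }
  # residual variances and autoregressions always survive
  expect_identical(sum(pruned@estimates$type == "residual_var"), 4L)
  expect_identical(sum(pruned@estimates$type == "lagged" &
                         pruned@estimates$i == pruned@estimates$j), 4L)

  # strongly supported structural paths survive pruning
  tr3 <- threePathTruth(seed = 17L)
  emb3 <- simEmbed(tr3, 400, seed = 17L)
  m3 <- fitUSEM(usemSpec(4, emb3$varNames,
                         freeA = rbind(c(2, 1), c(4, 3)),
                         freePhi = rbind(c(3, 2))),
                cov(emb3$data), emb3$N)
  p3 <- pruneNonsignificant(m3)
  expect_identical(nrow(p3@spec@freeA), 2L)
  expect_identical(nrow(p3@spec@freePhi), 1L)
  # everything still freed is significant (apart from the exempt terms)
  keep <- p3@estimates[p3@estimates$type == "contemporaneous" |
                         (p3@estimates$type == "lagged" &
                            p3@estimates$i != p3@estimates$j), ]
  expect_true(all(keep$p < 0.05))
})

test_that("standardized paths preserve exactness, bounds and signs", {
  # population covariance of a unit-variance truth: standardized == raw
  A <- matrix(0, 2, 2); A[2, 1] <- 0.4
  tr <- standardizedUSEMTruth(A, diag(0.3, 2), seed = 18L)
  B <- solve(diag(2) - tr@A)
  M <- B %*% tr@Phi
  Sig <- diag(2)
  for (i in 1:400) Sig <- M %*% Sig %*% t(M) + B %*% tr@Psi %*% t(B)
  Syx <- M %*% Sig
  S <- rbind(cbind(Sig, t(Syx)), cbind(Syx, Sig))
  fit <- fitUSEM(usemSpec(2, freeA = rbind(c(2, 1))), S, N = 500L)
  expect_lt(abs(fit@standardizedA[2, 1] - fit@A[2, 1]), 1e-6)
  expect_lt(abs(fit@A[2, 1] - 0.4), 1e-6)

  tr4 <- threePathTruth(seed = 19L)
  emb <- simEmbed(tr4, 200, seed = 19L)
  m <- fitUSEM(usemSpec(4, emb$varNames,
                        freeA = rbind(c(2, 1)), freePsi = rbind(c(1, 3))),
               cov(emb$data), emb$N)
  sp <- standardizedPaths(m)
  expect_true(all(abs(sp$residCor) <= 1))
  expect_identical(sign(sp$A[2, 1]), sign(m@A[2, 1]))
  expect_identical(sign(sp$Phi), sign(m@Phi))
})

test_that("network export writes canonical edges and reimports to the same matrices", {
  tr <- threePathTruth(seed = 20L)
  emb <- simEmbed(tr, 120, seed = 20L)
  res <- forwardSearch(emb$data, N = emb$N, varNames = emb$varNames)
  path <- tempfile(fileext = ".csv")
  exportNetwork(res$model, path, trace = res$trace)
  edges <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(edges), c("from", "to", "type", "weight", "se", "p"))
  expect_equal(edges$weight, networkEdges(res$model)$weight,
               tolerance = 1e-15)
  # residual_cov rows come in canonical (index-ordered) pairs
  vn <- emb$varNames
  cov_rows <- edges[edges$type == "residual_cov", ]
  if (nrow(cov_rows))
    expect_true(all(match(cov_rows$from, vn) < match(cov_rows$to, vn)))
  # reimport reconstructs the standardized matrices
  reA <- matrix(0, 4, 4, dimnames = list(vn, vn))
  rePhi <- matrix(0, 4, 4, dimnames = list(vn, vn))
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    if (e$type == "contemporaneous") reA[e$to, e$from] <- e$weight
    if (e$type == "lagged") rePhi[e$to, e$from] <- e$weight
  }
  expect_equal(reA, res$model@standardizedA, tolerance = 1e-12)
  expect_equal(rePhi, res$model@standardizedPhi, tolerance = 1e-12)
  # JSON report parses and flags the pruning convention
  rep <- jsonlite::read_json(paste0(path, ".json"))
  expect_true(rep$pruned)
  expect_identical(rep$chi2_multiplier, "N-1")
  expect_true(rep$trace$stop_reason %in%
                c("fit_excellent", "no_significant_candidate",
                  "max_steps", "estimation_failure"))

  # an empty structural model exports autoregressive rows only
  m0 <- fitUSEM(usemSpec(4, emb$varNames), cov(emb$data), emb$N)
  e0 <- networkEdges(m0)
  expect_identical(nrow(e0), 4L)
  expect_true(all(e0$type == "lagged" & e0$from == e0$to))
})
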