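test_that("reading a long diary CSV builds the study, masks blanks, and validates", {
  path <- writeToyDiary()
  study <- readDiary(path, srisScales())
  expect_s4_class(study, "DailyStudy")
  expect_identical(personIds(study), c("p1", "p2"))
  expect_identical(study@studyLength, 3L)
  p1 <- getPerson(study, "p1")
  expect_identical(length(seriesDays(p1)), 3L)
  # blank masculinity cell on day 2 -> mask false there, others true
  expect_false(seriesObserved(p1)[2, "masculinity"])
  expect_true(all(seriesObserved(p1)[, "femininity"]))
  expect_identical(seriesValues(p1)[, "femininity"], c(3, 4, 5))

  # out-of-range value rejected with person/day/variable named
  bad <- tempfile(fileext = ".csv")
  writeLines(c("person_id,day,femininity", "p1,1,6"), bad)
  expect_error(readDiary(bad, srisScales()["femininity"]),
               "p1.*day 1.*femininity")

  # duplicate (person, day) rejected
  dup <- tempfile(fileext = ".csv")
  writeLines(c("person_id,day,femininity", "p1,1,3", "p1,1,4"), dup)
  expect_error(readDiary(dup, srisScales()["femininity"]), "duplicate")

  # malformed file names the problem
  expect_error(readDiary(path, list(recall = scaleSpec("recall", 0, 5))),
               "not found")
})

test_that("write -> read round trip reproduces doubles, masks and phase exactly", {
  set.seed(11)
  vals <- matrix(runif(40, 1, 5), 20, 2,
                 dimnames = list(NULL, c("femininity", "masculinity")))
  vals[c(3, 9), ] <- NA
  vals[15, 2] <- NA
  phase <- rep(c(1L, 0L), 10)
  phase[c(3, 9)] <- NA
  s <- personSeries("w01", vals, phase = phase, scales = srisScales())
  study <- dailyStudy(list(s))
  path <- tempfile(fileext = ".csv")
  writeDiary(study, path)
  back <- readDiary(path, srisScales())
  p <- getPerson(back, "w01")
  expect_identical(seriesValues(p), seriesValues(s))
  expect_identical(seriesObserved(p), seriesObserved(s))
  expect_identical(seriesPhase(p), seriesPhase(s))
  # scale sidecar round trip
  schema <- readScaleSchema(paste0(path, ".scales.json"))
  expect_identical(schema$femininity@min, 1)
  expect_identical(schema$femininity@max, 5)

  # a second write is byte-identical
  path2 <- tempfile(fileext = ".csv")
  writeDiary(study, path2, schemaPath = NA)
  expect_identical(readLines(path), readLines(path2))
})

test_that("response rate counts observed days over the nominal length", {
  vals <- matrix(NA_real_, 100, 1, dimnames = list(NULL, "femininity"))
  vals[1:80, 1] <- 3
  s <- makeSeries(vals)
  expect_identical(responseRate(s, "femininity"), 0.80)
  full <- makeSeries(matrix(2, 75, 1, dimnames = list(NULL, "femininity")))
  expect_identical(responseRate(full, "femininity"), 1.0)
  none <- personSeries("p0", matrix(NA_real_, 100, 1,
                                    dimnames = list(NULL, "femininity")))
  expect_identical(responseRate(none, "femininity"), 0.0)

  # invariance to CSV row order
  path <- writeToyDiary()
  raw <- read.csv(path)
  shuffled <- tempfile(fileext = ".csv")
  write.csv(raw[c(4, 2, 6, 1, 5, 3), ], shuffled, row.names = FALSE,
            na = "")
  a <- readDiary(path, srisScales())
  b <- readDiary(shuffled, srisScales())
  expect_identical(responseRate(getPerson(a, "p1"), "masculinity"),
                   responseRate(getPerson(b, "p1"), "masculinity"))
})

test_that("compliance filtering keeps the 80% boundary and logs exclusions", {
  mk <- function(id, nObs) {
    v <- matrix(NA_real_, 100, 1, dimnames = list(NULL, "femininity"))
    v[seq_len(nObs), 1] <- 3
    personSeries(id, v)
  }
  study <- dailyStudy(list(mk("keep", 80), mk("drop", 79)),
                      studyLength = 100L)
  expect_message(kept <- filterCompliance(study), "drop")
  expect_identical(personIds(kept), "keep")
  empty <- filterCompliance(dailyStudy(list(), studyLength = 10L))
  expect_identical(nPersons(empty), 0L)
})

test_that("daily composites average items with the conservative missing rule", {
  vals <- cbind(f1 = c(3, 5, 2), f2 = c(4, NA, 2), f3 = c(5, 4, 2))
  scales <- list(f1 = scaleSpec("f1", 1, 5), f2 = scaleSpec("f2", 1, 5),
                 f3 = scaleSpec("f3", 1, 5))
  s <- personSeries("p1", vals, scales = scales)
  out <- computeComposite(s, c("f1", "f2", "f3"), "femininity")
  expect_identical(unname(seriesValues(out)[, "femininity"]),
                   c(4, NA, 2))
  # configurable mean-of-available rule
  avail <- computeComposite(s, c("f1", "f2", "f3"), "femininity",
                            rule = "available")
  expect_identical(unname(seriesValues(avail)[2, "femininity"]), 4.5)
  expect_error(computeComposite(s, c("f1", "nope"), "x"), "unknown item")
  # items on different scales refused
  vals2 <- cbind(f1 = c(3, 5, 2), f2 = c(1, 0, 2), f3 = c(5, 4, 2))
  s2 <- personSeries("p1", vals2,
                     scales = list(f1 = scaleSpec("f1", 1, 5),
                                   f2 = scaleSpec("f2", 0, 2),
                                   f3 = scaleSpec("f3", 1, 5)))
  expect_error(computeComposite(s2, c("f1", "f2", "f3"), "x"),
               "share one scale")
})

test_that("lag embedding pairs consecutive calendar days and counts drops", {
  v <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  s <- makeSeries(v)
  emb <- lagEmbed(s, c("a", "b"), minPairs = 2L)
  expect_identical(emb$N, 4L)
  expect_identical(dim(emb$data), c(4L, 4L))
  expect_identical(colnames(emb$data), c("a_lag", "b_lag", "a", "b"))
  expect_identical(unname(emb$data[, "a"]), v[2:5, "a"])
  expect_identical(unname(emb$data[, "a_lag"]), v[1:4, "a"])

  # day 3 missing leaves only pairs (1,2) and (4,5) -> default guard errors
  v2 <- v; v2[3, ] <- NA
  s2 <- makeSeries(v2)
  expect_error(lagEmbed(s2, c("a", "b")), "insufficient complete pairs")
  emb2 <- lagEmbed(s2, c("a", "b"), minPairs = 2L)
  expect_identical(emb2$N, 2L)
  expect_identical(unname(emb2$data[, "a"]), v[c(2, 5), "a"])

  # fully observed long series: N = T - lag
  big <- makeSeries(matrix(rnorm(100), 100, 1, dimnames = list(NULL, "a")))
  expect_identical(lagEmbed(big, "a")$N, 99L)

  # each dropped interior day removes at most lag + 1 pairs
  for (d in c(10, 50, 99)) {
    vv <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "a"))
    vv[d, ] <- NA
    expect_gte(lagEmbed(makeSeries(vv), "a")$N, 99L - 2L)
  }
})

test_that("column standardization is exact, guarded and invertible", {
  m <- cbind(x = c(1, 2, 3), y = c(5, 1, 0))
  z <- standardizeColumns(m)
  expect_equal(unname(z$scaled[, "x"]), c(-1, 0, 1))
  expect_equal(colMeans(z$scaled), c(x = 0, y = 0))
  expect_equal(apply(z$scaled, 2, sd), c(x = 1, y = 1))
  expect_error(standardizeColumns(cbind(k = rep(2, 5))), "k")
  set.seed(2)
  m2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  z2 <- standardizeColumns(m2)
  expect_lt(max(abs(unstandardizeColumns(z2) - m2)), 1e-12)
})
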