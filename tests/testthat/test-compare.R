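# small helper: an InfectionPattern with a prescribed dense C
.patternFrom <- function(M, nodes) {
  p <- new("InfectionPattern")
  p@C <- as(as(as(Matrix::Matrix(M, sparse = TRUE), "dMatrix"),
               "generalMatrix"), "CsparseMatrix")
  p@nRuns <- 1L
  p@timeCutoff <- Inf
  p@mechanismFilter <- "all"
  p@nodes <- nodes
  validObject(p)
  p
}

test_that("cosine similarity matches hand-computed values", {
  nodes <- c("a", "b")
  id <- .patternFrom(matrix(c(0, 0.3, 0.7, 0), 2), nodes)
  expect_equal(cosineSimilarity(id, id), 1)
  e1 <- .patternFrom(matrix(c(0, 0, 1, 0), 2), nodes)  # only a -> b
  e2 <- .patternFrom(matrix(c(0, 1, 0, 0), 2), nodes)  # only b -> a
  expect_equal(cosineSimilarity(e1, e2), 0)
  both <- .patternFrom(matrix(c(0, 1, 1, 0), 2), nodes)
  expect_equal(cosineSimilarity(e1, both), 1 / sqrt(2))
  zero <- .patternFrom(matrix(0, 2, 2), nodes)
  expect_error(cosineSimilarity(e1, zero), "all-zero")
  other <- .patternFrom(matrix(c(0, 1, 0, 0), 2), c("x", "y"))
  expect_error(cosineSimilarity(e1, other), "node index")
})

test_that("rank agreement reproduces the brute-force Kendall values", {
  mk <- function(s) data.frame(node = c("a", "b", "c"), spreader = s,
                               receiver = rev(s))
  i1 <- mk(c(3, 2, 1))
  expect_equal(rankAgreement(i1, i1, "spreader"), 1)
  expect_equal(rankAgreement(i1, mk(c(1, 2, 3)), "spreader"), -1)
  expect_equal(rankAgreement(i1, mk(c(3, 1, 2)), "spreader"), 1 / 3)
  # order of rows must not matter
  shuffled <- mk(c(3, 1, 2))[c(2, 3, 1), ]
  expect_equal(rankAgreement(i1, shuffled, "spreader"), 1 / 3)
  expect_error(rankAgreement(i1, mk(c(1, 1, 1)), "spreader"), "constant")
  expect_error(rankAgreement(i1, data.frame(node = "z", spreader = 1,
                                            receiver = 1), "spreader"),
               "node set")
})

test_that("experiment configs validate their inputs", {
  g <- smallSchoolGraph()
  cond <- list(label = "sir", params = simpleParams("SIR", beta = 1))
  expect_error(experimentConfig(g, list(), 10, 1), "conditions")
  expect_error(experimentConfig(g, list(cond, cond), 10, 1), "unique")
  expect_error(experimentConfig(g, list(cond), 10, 1,
                                window = c(0.9, 0.5)))
  cfg <- experimentConfig(g, list(cond), 10, 1)
  expect_s3_class(cfg, "ExperimentConfig")
})

test_that("cross-condition similarity is symmetric with unit diagonal", {
  g <- smallSchoolGraph()
  cfg <- experimentConfig(
    g,
    list(list(label = "sirA", params = simpleParams("SIR", beta = 1.5)),
         list(label = "sirB", params = simpleParams("SIR", beta = 1.5)),
         list(label = "thr", params = thresholdParams(theta = 0.25))),
    nRuns = 30, rngSeed = 77)
  out <- crossConditionSimilarity(cfg)
  S <- out$similarity
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  # two independent estimates of the same condition resemble each other
  # more than a different mechanism does
  expect_gt(S["sirA", "sirB"], S["sirA", "thr"])
})

test_that("conditioning resamples to quota or reports the shortfall", {
  g <- smallSchoolGraph()
  cfg <- experimentConfig(
    g, list(list(label = "sir", params = simpleParams("SIR", beta = 2))),
    nRuns = 15, rngSeed = 5, window = c(0.5, 1))
  out <- crossConditionSimilarity(cfg)
  expect_equal(nRuns(out$runs[[1]]), 15L)
  expect_true(all(runSummaries(out$runs[[1]])$attackRate >= 0.5))
  # an unreachable window exhausts the attempt ceiling with a clear error
  cfgBad <- experimentConfig(
    g, list(list(label = "sir", params = simpleParams("SIR", beta = 0))),
    nRuns = 5, rngSeed = 5, window = c(0.5, 1), maxAttemptFactor = 3)
  expect_error(crossConditionSimilarity(cfgBad), "ceiling")
})

test_that("experiment artifacts are persisted with a manifest", {
  g <- smallSchoolGraph()
  dir <- file.path(tempfile(), "exp")
  cfg <- experimentConfig(
    g,
    list(list(label = "sir", params = simpleParams("SIR", beta = 1.5)),
         list(label = "covid", params = covidParams(beta = 0.5))),
    nRuns = 10, rngSeed = 3, outDir = dir)
  out <- crossConditionSimilarity(cfg)
  expect_true(file.exists(file.path(dir, "similarity.csv")))
  expect_true(file.exists(file.path(dir, "pattern_sir.tsv")))
  expect_true(file.exists(file.path(dir, "summaries_covid.csv")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$rngSeed, 3)
  expect_equal(man$labels, c("sir", "covid"))
  S <- as.matrix(read.csv(file.path(dir, "similarity.csv"),
                          row.names = 1))
  expect_equal(unname(S), unname(out$similarity))
})

test_that("time-matched similarity returns aligned curves and modes", {
  g <- smallSchoolGraph()
  ref <- runSimulations(g, simpleParams("SIR", beta = 3), 40, rngSeed = 55)
  tst <- runSimulations(g, simpleParams("SIR", beta = 1.2), 40,
                        rngSeed = 56)
  tEnd <- max(runSummaries(ref)$endTime) + 1
  grid <- seq(0.5, tEnd, length.out = 40)
  tm <- timeMatchedSimilarity(ref, list(low = tst), grid)
  expect_equal(dim(tm$similarity), c(length(grid), 1L))
  expect_equal(colnames(tm$similarity), "low")
  ok <- !is.na(tm$similarity)
  expect_true(all(tm$similarity[ok] >= 0 & tm$similarity[ok] <= 1 + 1e-12))
  expect_true(tm$argmaxTime %in% grid)
  # the reference self-comparison plateaus near its final similarity
  self <- timeMatchedSimilarity(ref, list(self = ref), grid)
  expect_equal(self$similarity[length(grid), 1],
               cosineSimilarity(buildInfectionPattern(ref),
                                buildInfectionPattern(ref)))
  expect_error(timeMatchedSimilarity(ref, list(tst), c(3, 1)), "sorted")
})
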