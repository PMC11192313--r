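test_that("C averages attributed fractions over all runs", {
  g <- makeToyGraph("two_node")
  runs <- runSimulations(g, simpleParams("SIR", beta = 1, muI = 1),
                         nRuns = 400, rngSeed = 31, seedNode = "a")
  p <- buildInfectionPattern(runs)
  C <- patternMatrix(p)
  nHit <- sum(runSummaries(runs)$attackRate == 1)
  expect_equal(C[1, 2], nHit / 400)
  expect_equal(C[2, 1], 0)
  expect_equal(nRuns(p), 400L)
})

test_that("the conservation law holds for every model family", {
  g <- smallSchoolGraph()
  hg <- smallSchoolHypergraph()
  runsList <- list(
    runSimulations(g, simpleParams("SIR", beta = 1), 15, rngSeed = 41),
    runSimulations(g, covidParams(beta = 0.5), 10, rngSeed = 42),
    runSimulations(hg, simplicialParams(0.5, 2), 10, rngSeed = 43),
    runSimulations(g, thresholdParams(theta = 0.2), 15, rngSeed = 44))
  for (runs in runsList)
    expect_lt(conservationGap(runs), 1e-9)
})

test_that("receiver indices never exceed 1 and match column sums", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SIR", beta = 2), 30, rngSeed = 17)
  p <- buildInfectionPattern(runs)
  idx <- nodeIndices(p)
  expect_equal(idx$node, graphNodes(g))
  expect_true(all(idx$receiver <= 1 + 1e-12))
  expect_equal(idx$spreader, unname(Matrix::rowSums(patternMatrix(p))))
  expect_equal(sum(idx$spreader), sum(idx$receiver))
})

test_that("time cutoffs give entrywise non-decreasing patterns", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SIR", beta = 2), 20, rngSeed = 19)
  grid <- c(2, 5, 10, 20, Inf)
  curve <- timePatternCurve(runs, grid)
  expect_named(curve, as.character(grid))
  for (k in seq_along(grid)[-1]) {
    d <- patternMatrix(curve[[k]]) - patternMatrix(curve[[k - 1]])
    expect_true(all(d@x >= -1e-15))
  }
  expect_equal(patternMatrix(curve[["Inf"]]),
               patternMatrix(buildInfectionPattern(runs)))
  expect_error(timePatternCurve(runs, c(5, 2)), "sorted")
})

test_that("mechanism filters decompose the simplicial pattern", {
  hg <- smallSchoolHypergraph()
  runs <- runSimulations(hg, simplicialParams(0.6, 3), 20, rngSeed = 23)
  full <- patternMatrix(buildInfectionPattern(runs))
  link <- patternMatrix(buildInfectionPattern(runs,
                                              mechanismFilter = "link"))
  triad <- patternMatrix(buildInfectionPattern(runs,
                                               mechanismFilter = "triad"))
  expect_equal(full, link + triad)
})

test_that("attack-rate filtering keeps the closed window and renumbers", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SIR", beta = 1.5), 40,
                         rngSeed = 29)
  f <- filterRunsByAttackRate(runs, 0.5, 1)
  sm <- runSummaries(f)
  expect_true(all(sm$attackRate >= 0.5))
  expect_equal(sm$run, seq_len(nrow(sm)))
  expect_equal(attr(f, "kept"),
               sum(runSummaries(runs)$attackRate >= 0.5))
  ev <- runEvents(f)
  if (nrow(ev)) expect_true(all(ev$run %in% sm$run))
})

test_that("bindRuns concatenates and preserves the conservation law", {
  g <- smallSchoolGraph()
  a <- runSimulations(g, simpleParams("SIR", beta = 1), 7, rngSeed = 5)
  b <- runSimulations(g, simpleParams("SIR", beta = 1), 8, rngSeed = 6)
  ab <- bindRuns(a, b)
  expect_equal(nRuns(ab), 15L)
  expect_equal(runSummaries(ab)$run, 1:15)
  expect_lt(conservationGap(ab), 1e-9)
  Ca <- patternMatrix(buildInfectionPattern(a))
  Cb <- patternMatrix(buildInfectionPattern(b))
  Cab <- patternMatrix(buildInfectionPattern(ab))
  expect_equal(Cab, (7 * Ca + 8 * Cb) / 15)
})

test_that("attackRateMode picks the non-zero mode and handles edge cases", {
  rates <- c(rep(0.01, 30), rep(0.63, 10), rep(0.65, 25), rep(0.81, 5))
  expect_equal(attackRateMode(rates), 0.65)
  expect_true(is.na(attackRateMode(rep(0.05, 50))))
  expect_error(attackRateMode(numeric()), "no attack rates")
  expect_error(attackRateMode(rates, binWidth = 0), "positive")
})

test_that("attackRateAtTime counts the seed and grows to the final rate", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SIR", beta = 2), 10, rngSeed = 37)
  a0 <- attackRateAtTime(runs, 0)
  expect_equal(a0, rep(1 / length(graphNodes(g)), 10))
  aEnd <- attackRateAtTime(runs, Inf)
  expect_equal(aEnd, runSummaries(runs)$attackRate)
  aMid <- attackRateAtTime(runs, 5)
  expect_true(all(aMid >= a0 & aMid <= aEnd))
})

test_that("patterns and node indices export to parseable text", {
  g <- makeToyGraph("two_node")
  runs <- runSimulations(g, simpleParams("SIR", beta = 3, muI = 0.5),
                         nRuns = 50, rngSeed = 2, seedNode = "a")
  p <- buildInfectionPattern(runs)
  pp <- tempfile(); np <- tempfile()
  writePattern(p, pp)
  writeNodeIndices(p, np)
  tab <- read.delim(pp)
  expect_equal(names(tab), c("i", "j", "C_ij"))
  expect_equal(sum(tab$C_ij), sum(patternMatrix(p)))
  idx <- read.csv(np)
  expect_equal(idx$spreader, nodeIndices(p)$spreader)
})
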