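test_that("simplicial with betaTriad = 0 behaves like a pairwise process", {
  hg <- triangleHypergraph()
  runs <- runSimulations(hg, simplicialParams(betaLink = 3, betaTriad = 0),
                         nRuns = 200, rngSeed = 5)
  expect_true(all(runEvents(runs)$mechanism == "link"))
  expect_true(all(runEvents(runs)$fraction == 1))
})

test_that("triadic infections are attributed 1/2 + 1/2 to the pair", {
  hg <- triangleHypergraph()
  runs <- runSimulations(hg, simplicialParams(betaLink = 0, betaTriad = 50,
                                              muI = 1),
                         nRuns = 100, rngSeed = 7, seedNode = c("a", "b"))
  ev <- runEvents(runs)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$mechanism == "triad"))
  expect_true(all(ev$fraction == 0.5))
  expect_true(all(ev$infectee == 3L))
  # each triadic event appears as exactly two half-attributed rows
  expect_true(all(table(ev$run) == 2L))
  expect_equal(sort(unique(ev$infector)), c(1L, 2L))
})

test_that("the triangle triadic infection probability matches the oracle", {
  # with betaLink = 0 the third node is infected iff the triadic clock
  # (rate betaTriad) beats the first of the two recoveries (rate 2 muI)
  hg <- triangleHypergraph()
  runs <- runSimulations(hg, simplicialParams(betaLink = 0, betaTriad = 2,
                                              muI = 1),
                         nRuns = 4000, rngSeed = 21, seedNode = c("a", "b"))
  pHat <- mean(runSummaries(runs)$attackRate == 1)
  p0 <- 2 / (2 + 2)
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(pHat - p0), 4 * se)
})

test_that("triadic infection needs both other members infectious", {
  hg <- triangleHypergraph()
  runs <- runSimulations(hg, simplicialParams(betaLink = 0, betaTriad = 50),
                         nRuns = 50, rngSeed = 3, seedNode = "a")
  # a single infectious node activates no triad and no link (betaLink = 0)
  expect_equal(nrow(runEvents(runs)), 0L)
})

test_that("threshold attribution is proportional to link weights", {
  g <- makeToyGraph("star", size = 3, weights = c(1, 1 / 3))
  runs <- runSimulations(g, thresholdParams(theta = 0.5),
                         nRuns = 1, rngSeed = 1,
                         seedNode = c("leaf1", "leaf2"))
  ev <- runEvents(runs)
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$mechanism == "threshold"))
  expect_equal(ev$infectee, c(1L, 1L))
  got <- ev$fraction[order(ev$infector)]
  expect_equal(got, c(3 / 4, 1 / 4))
})

test_that("the threshold comparison is strict and uses a static denominator", {
  g <- makeToyGraph("star", size = 3, weights = c(1, 1))
  # hub fraction is exactly 1/2 with one infectious leaf: no infection
  r <- runSimulations(g, thresholdParams(theta = 0.5), nRuns = 1,
                      rngSeed = 1, seedNode = "leaf1")
  expect_equal(nrow(runEvents(r)), 0L)
  # just below 1/2 the hub is infected in the first step
  r2 <- runSimulations(g, thresholdParams(theta = 0.49), nRuns = 1,
                       rngSeed = 1, seedNode = "leaf1")
  ev <- runEvents(r2)
  expect_equal(ev$infectee[1], 1L)
  expect_equal(ev$time[1], 1)
})

test_that("threshold cascades propagate along a uniform chain", {
  g <- makeToyGraph("chain", size = 6)
  # interior nodes have two equal links: one infectious neighbour gives
  # fraction 1/2 > 0.4, so the cascade travels the whole chain while the
  # recovery is slow
  runs <- runSimulations(g, thresholdParams(theta = 0.4, muI = 0.01),
                         nRuns = 1, rngSeed = 2, seedNode = "a")
  expect_equal(runSummaries(runs)$attackRate, 1)
  ev <- runEvents(runs)
  expect_equal(ev$time, 1:5)  # one hop per synchronous step
})

test_that("threshold runs terminate with every infected node recovered", {
  g <- makeToyGraph("chain", size = 6)
  runs <- runSimulations(g, thresholdParams(theta = 0.4, muI = 0.5),
                         nRuns = 20, rngSeed = 8)
  st <- stageHistory(runs)
  nI <- sum(st$stage == "I")
  nR <- sum(st$stage == "R")
  expect_equal(nI, nR)
  # above 1/2 an interior chain node can never be tipped by one neighbour
  quiet <- runSimulations(g, thresholdParams(theta = 0.6), nRuns = 5,
                          rngSeed = 9, seedNode = "a")
  expect_equal(nrow(runEvents(quiet)), 0L)
})

test_that("simplicial runs satisfy the class invariants", {
  hg <- smallSchoolHypergraph()
  runs <- runSimulations(hg, simplicialParams(betaLink = 0.6,
                                              betaTriad = 2),
                         nRuns = 20, rngSeed = 13)
  expect_true(validObject(runs))
  ev <- runEvents(runs)
  expect_true(all(ev$mechanism %in% c("link", "triad")))
  if (any(ev$mechanism == "triad"))
    expect_true(all(ev$fraction[ev$mechanism == "triad"] == 0.5))
})
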