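test_that("parameter constructors apply presets and validate", {
  p <- simpleParams("SIR")
  expect_equal(p@muI, 0.25)
  expect_true(is.na(p@muE))
  p <- simpleParams("SEIRe4")
  expect_equal(p@muE, 0.25)
  expect_equal(p@muI, 1)
  p <- simpleParams("SEIRi4v025")
  expect_equal(c(p@muI, p@muE, p@etaE, p@etaI), c(0.25, 1, 0.25, 0.25))
  expect_equal(simpleParams("SIR", muI = 2)@muI, 2)
  expect_error(simpleParams("SIR", beta = -1), "beta")
  expect_error(simpleParams("SEIRe1", etaI = 2), "etaI")
  expect_error(covidParams(pC = 1.5), "pC")
})

test_that("stage courses have the advertised structure and moments", {
  sir <- sampleStageDurations(simpleParams("SIR"), n = 4000, rngSeed = 1)
  expect_true(all(sir$stage == "I"))
  expect_equal(mean(sir$duration), 4, tolerance = 0.05)
  expect_equal(sd(sir$duration), 4, tolerance = 0.1)

  lowVar <- sampleStageDurations(simpleParams("SEIRe1v025"), n = 4000,
                                 rngSeed = 2)
  iDur <- lowVar$duration[lowVar$stage == "I"]
  expect_equal(mean(iDur), 1, tolerance = 0.05)
  expect_equal(sd(iDur), 0.25, tolerance = 0.1)
  expect_true(all(lowVar$r[lowVar$stage == "E"] == 0))

  cov <- sampleStageDurations(covidParams(), n = 4000, rngSeed = 3)
  expect_true(all(cov$stage[!duplicated(cov$sample)] == "E"))
  last <- cov[!duplicated(cov$sample, fromLast = TRUE), ]
  expect_equal(mean(last$stage == "Ic"), 0.5, tolerance = 0.05)
  expect_true(all(last$r[last$stage == "Ic"] == 1))
  expect_true(all(last$r[last$stage == "Isc"] == 0.55))
  expect_equal(mean(cov$duration[cov$stage == "E"]), 4, tolerance = 0.1)
})

test_that("runs are reproducible and independent of run count prefix", {
  g <- smallSchoolGraph()
  p <- simpleParams("SIR", beta = 1)
  r1 <- runSimulations(g, p, nRuns = 5, rngSeed = 9)
  r2 <- runSimulations(g, p, nRuns = 5, rngSeed = 9)
  expect_identical(runEvents(r1), runEvents(r2))
  expect_identical(runSummaries(r1), runSummaries(r2))
  r3 <- runSimulations(g, p, nRuns = 5, rngSeed = 10)
  expect_false(identical(runSummaries(r1), runSummaries(r3)))
})

test_that("a seed is never re-infected and infections form a forest", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SEIRe1", beta = 2), nRuns = 10,
                         rngSeed = 4)
  ev <- runEvents(runs)
  sm <- runSummaries(runs)
  expect_false(any(ev$infectee == sm$seed[ev$run]))
  # each node infected at most once per run, with a single infector
  expect_false(anyDuplicated(paste(ev$run, ev$infectee)) > 0)
  expect_true(all(ev$fraction == 1))
  # infectors were themselves infected (or seeded) before the event
  infTime <- ev$time[match(paste(ev$run, ev$infector),
                           paste(ev$run, ev$infectee))]
  infTime[is.na(infTime)] <- 0  # seeds are infectious from time 0
  expect_true(all(infTime < ev$time))
})

test_that("stage history matches drawn courses (E before I before R)", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SEIRe4", beta = 2), nRuns = 3,
                         rngSeed = 6)
  st <- stageHistory(runs)
  byNode <- split(st, paste(st$run, st$node))
  for (h in byNode) {
    h <- h[order(h$time), ]
    expect_equal(h$stage, c("E", "I", "R"))
  }
})

test_that("beta = 0 never transmits", {
  g <- smallSchoolGraph()
  runs <- runSimulations(g, simpleParams("SIR", beta = 0), nRuns = 5,
                         rngSeed = 2)
  expect_equal(nrow(runEvents(runs)), 0L)
  expect_true(all(runSummaries(runs)$attackRate ==
                    1 / length(graphNodes(g))))
})

test_that("seedNode accepts ids, indices and vectors", {
  g <- makeToyGraph("chain", size = 4)
  r <- runSimulations(g, simpleParams("SIR", beta = 5), nRuns = 3,
                      rngSeed = 1, seedNode = "b")
  expect_true(all(runSummaries(r)$seed == 2L))
  r2 <- runSimulations(g, simpleParams("SIR", beta = 5), nRuns = 3,
                       rngSeed = 1, seedNode = 2L)
  expect_identical(runSummaries(r), runSummaries(r2))
  expect_error(runSimulations(g, simpleParams("SIR"), 1, 1,
                              seedNode = "zz"), "not found")
})

test_that("two-node infection probability tracks beta/(beta+mu) (quick)", {
  g <- makeToyGraph("two_node")
  runs <- runSimulations(g, simpleParams("SIR", beta = 0.75, muI = 0.25),
                         nRuns = 3000, rngSeed = 12, seedNode = "a")
  phat <- mean(runSummaries(runs)$attackRate == 1)
  expect_equal(phat, 0.75, tolerance = 0.05)
})

test_that("estimateR0 counts only the seed's direct infections", {
  g <- makeToyGraph("star", size = 5)
  # infinitely fast transmission from the hub infects all 4 leaves
  r0 <- estimateR0(g, simpleParams("SIR", muI = 0.25), beta = 1e6,
                   nRuns = 50, rngSeed = 3, detailed = TRUE)
  # at this rate transmission beats recovery almost surely, so a leaf seed
  # infects exactly the hub and a hub seed exactly its 4 leaves
  expect_true(all(r0$counts %in% c(1L, 4L)))
  expect_equal(r0$r0, (1 / 5) * 4 + (4 / 5) * 1, tolerance = 0.5)
  expect_error(estimateR0(g, simpleParams("SIR"), beta = -1, nRuns = 5,
                          rngSeed = 1), "beta")
})

test_that("calibrateBeta returns a monotone table and flags bad targets", {
  g <- makeToyGraph("two_node")
  p <- simpleParams("SIR", muI = 1)
  b <- calibrateBeta(g, p, targetR0 = 0.5, betaRange = c(0.25, 4),
                     nGrid = 6, runsPerPoint = 400, rngSeed = 8)
  tab <- attr(b, "table")
  expect_false(is.unsorted(tab$r0iso))
  expect_true(b > 0.25 && b < 4)
  expect_error(
    calibrateBeta(g, p, targetR0 = 50, betaRange = c(0.25, 4), nGrid = 4,
                  runsPerPoint = 100, rngSeed = 8),
    "achievable range")
})
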