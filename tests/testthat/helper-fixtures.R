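# shared fixtures, built lazily and cached for the whole test session
.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(name, build) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- build()
  .fixtureCache[[name]]
}

# a reduced school-like substrate for fast unit tests (the full default
# population is exercised in the acceptance tests)
smallSchoolEvents <- function() {
  .cached("smallEvents", function()
    generateSchoolLikeEvents(schoolLikeSpec(nGroups = 4, groupSize = 12,
                                            nSnapshots = 800, rngSeed = 11)))
}

smallSchoolGraph <- function() {
  .cached("smallGraph", function() aggregateWeightedGraph(smallSchoolEvents()))
}

smallSchoolHypergraph <- function() {
  .cached("smallHg", function() buildWeightedHypergraph(smallSchoolEvents()))
}

# full-size school-like substrate (generator defaults), for acceptance tests
defaultSchoolGraph <- function() {
  .cached("defGraph", function()
    aggregateWeightedGraph(generateSchoolLikeEvents(schoolLikeSpec())))
}

defaultSchoolHypergraph <- function() {
  .cached("defHg", function()
    buildWeightedHypergraph(generateSchoolLikeEvents(schoolLikeSpec())))
}

# fully connected weighted triangle with one triad of weight 1
triangleHypergraph <- function() {
  g <- new("WeightedContactGraph", nodes = c("a", "b", "c"),
           edges = data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                              n = 1, W = 1),
           nMax = 1)
  new("WeightedHypergraph", graph = g,
      triads = data.frame(i = 1L, j = 2L, k = 3L, n = 1L, W = 1),
      nMaxTriad = 1)
}

# sum(C) must equal the mean number of non-seed infections per run
conservationGap <- function(runs) {
  p <- buildInfectionPattern(runs)
  N <- length(graphNodes(runs))
  sm <- runSummaries(runs)
  abs(sum(patternMatrix(p)) - mean(sm$attackRate * N - 1))
}
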