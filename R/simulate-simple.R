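# adjacency list (neighbour indices + weights) of a weighted contact graph
.adjList <- function(graph) {
  N <- length(graph@nodes)
  ed <- graph@edges
  from <- c(ed$i, ed$j)
  to <- c(ed$j, ed$i)
  w <- c(ed$W, ed$W)
  f <- factor(from, levels = seq_len(N))
  list(nbr = split(to, f), wts = split(w, f))
}

# one event-driven realization of a simple-contagion process.
#
# Next-reaction scheme: when a node enters its course of disease, its stage
# durations are drawn, then one exponential transmission delay per
# (infectious stage, currently susceptible neighbour); delays landing inside
# the stage window become candidate infections. Only the earliest candidate
# per neighbour matters (in SIR-like dynamics a node never returns to S).
# Candidates are resolved in global time order, discarding those whose
# target is no longer susceptible. Exact for piecewise-constant hazards and
# free of discretization error for the gamma-distributed stage durations.
.simulateSimpleCore <- function(adj, params, seedIdx, tMax = Inf) {
  beta <- params@beta
  nbr <- adj$nbr
  wts <- adj$wts
  N <- length(nbr)
  sus <- rep(TRUE, N)
  infTime <- rep(NA_real_, N)
  infector <- rep(NA_integer_, N)
  recovery <- rep(NA_real_, N)
  stgNode <- integer(); stgName <- character(); stgTime <- numeric()
  qt <- numeric(); qs <- integer(); qg <- integer()

  doInfect <- function(node, tNow) {
    course <- .drawCourse(params)
    nStg <- length(course$stage)
    starts <- tNow + cumsum(c(0, course$duration[-nStg]))
    stgNode <<- c(stgNode, rep.int(node, nStg + 1L))
    stgName <<- c(stgName, course$stage, "R")
    stgTime <<- c(stgTime, starts, tNow + sum(course$duration))
    recovery[node] <<- tNow + sum(course$duration)
    nb <- nbr[[node]]
    w <- wts[[node]]
    keep <- sus[nb]
    nb <- nb[keep]
    w <- w[keep]
    if (!length(nb)) return(invisible(NULL))
    best <- rep(Inf, length(nb))
    for (s in seq_len(nStg)) {
      r <- course$r[s]
      if (r <= 0 || beta <= 0) next
      d <- stats::rexp(length(nb), rate = r * beta * w)
      hit <- d < course$duration[s]
      if (any(hit)) best[hit] <- pmin(best[hit], starts[s] + d[hit])
    }
    fin <- is.finite(best)
    if (any(fin)) {
      qt <<- c(qt, best[fin])
      qs <<- c(qs, rep.int(node, sum(fin)))
      qg <<- c(qg, nb[fin])
    }
    invisible(NULL)
  }

  for (s in seedIdx) {
    sus[s] <- FALSE
    infTime[s] <- 0
  }
  for (s in seedIdx) doInfect(s, 0)
  # tMax = NA: truncate at the seed's recovery (enough to count its direct
  # infections; the course is only known after seeding)
  if (is.na(tMax)) tMax <- recovery[seedIdx[1L]]

  while (length(qt)) {
    k <- which.min(qt)
    tNow <- qt[k]
    # candidates are processed in time order, so once the earliest one lies
    # beyond tMax nothing before tMax can still happen
    if (tNow > tMax) break
    src <- qs[k]; tgt <- qg[k]
    qt <- qt[-k]; qs <- qs[-k]; qg <- qg[-k]
    if (!sus[tgt]) next
    sus[tgt] <- FALSE
    infTime[tgt] <- tNow
    infector[tgt] <- src
    doInfect(tgt, tNow)
  }

  ev <- which(!is.na(infector))
  ord <- ev[order(infTime[ev])]
  infected <- which(!sus)
  list(evTime = infTime[ord], evTgt = ord, evSrc = infector[ord],
       evFrac = rep(1, length(ord)),
       evMech = rep("link", length(ord)),
       stgNode = stgNode, stgName = stgName, stgTime = stgTime,
       seed = seedIdx[1L], nInfected = length(infected),
       attackRate = length(infected) / N,
       endTime = if (length(infected)) max(recovery[infected]) else 0,
       seedRecovery = recovery[seedIdx[1L]])
}

.resolveSeed <- function(seedNode, nodes) {
  if (identical(seedNode, "random")) return(NA_integer_)
  idx <- if (is.numeric(seedNode)) as.integer(seedNode)
         else match(as.character(seedNode), nodes)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(nodes)))
    stop("seed node not found in the substrate")
  idx
}

.coreRunner <- function(substrate, params) {
  if (is(params, "SimpleParams") || is(params, "CovidParams")) {
    graph <- if (is(substrate, "WeightedHypergraph")) substrate@graph
             else substrate
    stopifnot(is(graph, "WeightedContactGraph"))
    adj <- .adjList(graph)
    list(nodes = graph@nodes,
         run = function(seedIdx, tMax = Inf)
           .simulateSimpleCore(adj, params, seedIdx, tMax),
         model = if (is(params, "CovidParams")) "COVID" else params@modelKind)
  } else if (is(params, "SimplicialParams")) {
    stopifnot(is(substrate, "WeightedHypergraph"))
    pre <- .simplicialPrep(substrate)
    list(nodes = substrate@graph@nodes,
         run = function(seedIdx) .simulateSimplicialCore(pre, params,
                                                         seedIdx),
         model = "simplicial")
  } else if (is(params, "ThresholdParams")) {
    graph <- if (is(substrate, "WeightedHypergraph")) substrate@graph
             else substrate
    stopifnot(is(graph, "WeightedContactGraph"))
    pre <- .thresholdPrep(graph)
    list(nodes = graph@nodes,
         run = function(seedIdx) .simulateThresholdCore(pre, params,
                                                        seedIdx),
         model = "threshold")
  } else stop("unsupported parameter class: ", class(params))
}

.assembleRuns <- function(results, nodes, model) {
  nr <- length(results)
  cnt <- vapply(results, function(r) length(r$evTime), integer(1L))
  events <- data.frame(
    run = rep.int(seq_len(nr), cnt),
    time = unlist(lapply(results, `[[`, "evTime"), use.names = FALSE),
    infectee = unlist(lapply(results, `[[`, "evTgt"), use.names = FALSE),
    infector = unlist(lapply(results, `[[`, "evSrc"), use.names = FALSE),
    fraction = unlist(lapply(results, `[[`, "evFrac"), use.names = FALSE),
    mechanism = unlist(lapply(results, `[[`, "evMech"), use.names = FALSE))
  if (!nrow(events))
    events <- data.frame(run = integer(), time = numeric(),
                         infectee = integer(), infector = integer(),
                         fraction = numeric(), mechanism = character())
  scnt <- vapply(results, function(r) length(r$stgNode), integer(1L))
  stages <- data.frame(
    run = rep.int(seq_len(nr), scnt),
    node = unlist(lapply(results, `[[`, "stgNode"), use.names = FALSE),
    stage = unlist(lapply(results, `[[`, "stgName"), use.names = FALSE),
    time = unlist(lapply(results, `[[`, "stgTime"), use.names = FALSE))
  summaries <- data.frame(
    run = seq_len(nr),
    seed = vapply(results, `[[`, integer(1L), "seed"),
    attackRate = vapply(results, `[[`, numeric(1L), "attackRate"),
    endTime = vapply(results, `[[`, numeric(1L), "endTime"))
  new("ContagionRuns", events = events, summaries = summaries,
      stages = stages, nodes = nodes, model = model, nRuns = as.integer(nr))
}

#' Simulate stochastic contagion runs on a weighted substrate
#'
#' Dispatches on the parameter class: \linkS4class{SimpleParams} and
#' \linkS4class{CovidParams} run the event-driven simple-contagion simulator
#' on a weighted graph; \linkS4class{SimplicialParams} run the
#' continuous-time simplicial simulator on a weighted hypergraph;
#' \linkS4class{ThresholdParams} run the synchronous weighted threshold
#' model. One root seed drives the experiment; an independent per-run stream
#' is derived from it, so individual runs are reproducible.
#'
#' @param substrate a \linkS4class{WeightedContactGraph} (simple/threshold)
#'   or \linkS4class{WeightedHypergraph} (simplicial; its base graph is used
#'   for the other models).
#' @param params a model parameter object.
#' @param nRuns number of independent realizations.
#' @param rngSeed integer root seed.
#' @param seedNode "random" (a uniformly chosen seed per run), a node id, an
#'   integer node index, or a vector of ids/indices to start with several
#'   initially infectious nodes.
#' @return a \linkS4class{ContagionRuns} object.
#' @export
runSimulations <- function(substrate, params, nRuns, rngSeed,
                           seedNode = "random") {
  stopifnot(nRuns >= 1)
  runner <- .coreRunner(substrate, params)
  fixedSeed <- .resolveSeed(seedNode, runner$nodes)
  set.seed(as.integer(rngSeed))
  runSeeds <- sample.int(.Machine$integer.max, nRuns)
  N <- length(runner$nodes)
  results <- vector("list", nRuns)
  for (k in seq_len(nRuns)) {
    set.seed(runSeeds[k])
    sIdx <- if (anyNA(fixedSeed)) sample.int(N, 1L) else fixedSeed
    results[[k]] <- runner$run(sIdx)
  }
  .assembleRuns(results, runner$nodes, runner$model)
}

#' Simulate a single simple-contagion run
#'
#' Convenience wrapper around \code{\link{runSimulations}} with
#' \code{nRuns = 1}.
#'
#' @inheritParams runSimulations
#' @return a \linkS4class{ContagionRuns} object holding one run.
#' @export
simulateSimple <- function(substrate, params, seedNode = "random", rngSeed) {
  stopifnot(is(params, "SimpleParams") || is(params, "CovidParams"))
  runSimulations(substrate, params, nRuns = 1L, rngSeed = rngSeed,
                 seedNode = seedNode)
}

#' Estimate the basic reproduction number R0 by direct counting
#'
#' Runs \code{nRuns} realizations, each seeded at a uniformly random node,
#' and counts in each the infections directly attributed to the seed before
#' the seed's recovery; R0 is the mean of those counts.
#'
#' @param graph substrate graph.
#' @param params a \linkS4class{SimpleParams} or \linkS4class{CovidParams}
#'   object (its beta is overridden by \code{beta}).
#' @param beta transmission-rate scale at which to estimate R0.
#' @param nRuns number of runs (default 1000).
#' @param rngSeed integer root seed.
#' @param detailed if TRUE, return a list with the per-run counts as well.
#' @return the estimated R0 (or a list, if \code{detailed}).
#' @export
estimateR0 <- function(graph, params, beta, nRuns = 1000, rngSeed,
                       detailed = FALSE) {
  if (beta < 0) stop("beta must be >= 0")
  params@beta <- beta
  validObject(params)
  runner <- .coreRunner(graph, params)
  N <- length(runner$nodes)
  set.seed(as.integer(rngSeed))
  runSeeds <- sample.int(.Machine$integer.max, nRuns)
  counts <- integer(nRuns)
  truncated <- is(params, "SimpleParams") || is(params, "CovidParams")
  for (k in seq_len(nRuns)) {
    set.seed(runSeeds[k])
    res <- if (truncated) {
      # dynamics after the seed's recovery cannot change its direct
      # infections, so the realization is cut there
      runner$run(sample.int(N, 1L), tMax = NA_real_)
    } else runner$run(sample.int(N, 1L))
    counts[k] <- sum(res$evSrc == res$seed & res$evTime <= res$seedRecovery)
  }
  if (detailed) list(r0 = mean(counts), counts = counts) else mean(counts)
}

#' Calibrate the transmission rate beta to a target R0
#'
#' Estimates R0 on a log-spaced grid of beta values (1000 runs per grid
#' point by default), monotonizes the (beta, R0) table by isotonic
#' regression to absorb Monte Carlo noise, and returns the linearly
#' interpolated beta at the target R0.
#'
#' @param graph substrate graph.
#' @param params simple-contagion parameter object (beta is swept).
#' @param targetR0 desired basic reproduction number.
#' @param betaRange range spanned by the default log-spaced grid.
#' @param nGrid number of grid points (default 20).
#' @param betaGrid optional explicit grid overriding range/nGrid.
#' @param runsPerPoint runs per grid point (default 1000).
#' @param rngSeed integer root seed.
#' @return calibrated beta, with the (beta, R0, isotonic R0) table attached
#'   as attribute \code{"table"}.
#' @export
calibrateBeta <- function(graph, params, targetR0, betaRange = c(0.05, 5),
                          nGrid = 20, betaGrid = NULL, runsPerPoint = 1000,
                          rngSeed) {
  if (is.null(betaGrid))
    betaGrid <- exp(seq(log(betaRange[1]), log(betaRange[2]),
                        length.out = nGrid))
  betaGrid <- sort(betaGrid)
  set.seed(as.integer(rngSeed))
  gridSeeds <- sample.int(.Machine$integer.max, length(betaGrid))
  r0hat <- vapply(seq_along(betaGrid), function(g) {
    estimateR0(graph, params, beta = betaGrid[g], nRuns = runsPerPoint,
               rngSeed = gridSeeds[g])
  }, numeric(1L))
  r0iso <- stats::isoreg(log(betaGrid), r0hat)$yf
  if (targetR0 < min(r0iso) || targetR0 > max(r0iso))
    stop(sprintf(
      "target R0 = %.4g outside the achievable range [%.4g, %.4g] on this grid",
      targetR0, min(r0iso), max(r0iso)))
  beta <- stats::approx(x = r0iso, y = betaGrid, xout = targetR0,
                        ties = mean)$y
  attr(beta, "table") <- data.frame(beta = betaGrid, r0 = r0hat,
                                    r0iso = r0iso)
  beta
}
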