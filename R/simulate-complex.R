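# scatter-add x into an N-vector at (possibly repeated) indices
.accum <- function(N, idx, x) {
  out <- numeric(N)
  if (length(idx)) {
    tmp <- rowsum(x, idx)
    out[as.integer(rownames(tmp))] <- tmp
  }
  out
}

.simplicialPrep <- function(hg) {
  g <- hg@graph
  N <- length(g@nodes)
  ed <- g@edges
  tr <- hg@triads
  # per-node incidence: neighbours with link weights, and triads with the
  # two other members and the triad weight
  own <- c(ed$i, ed$j)
  oth <- c(ed$j, ed$i)
  ww <- c(ed$W, ed$W)
  f <- factor(own, levels = seq_len(N))
  eOther <- split(oth, f)
  eW <- split(ww, f)
  town <- c(tr$i, tr$j, tr$k)
  to1 <- c(tr$j, tr$i, tr$i)
  to2 <- c(tr$k, tr$k, tr$j)
  tw <- rep(tr$W, 3L)
  tf <- factor(town, levels = seq_len(N))
  list(N = N, ei = ed$i, ej = ed$j, ew = ed$W,
       ti = tr$i, tj = tr$j, tk = tr$k, tww = tr$W,
       eOther = eOther, eW = eW,
       tOther1 = split(to1, tf), tOther2 = split(to2, tf),
       tW = split(tw, tf))
}

# continuous-time simplicial SIR: susceptible i feels hazard
# betaLink * W[ij] from each infectious neighbour j plus betaTriad * W[ikl]
# from each triad whose other two members are both infectious. All clocks
# are exponential, so total-hazard redraws after every event are exact by
# memorylessness. Triadic infections are attributed 1/2 + 1/2 to the two
# infectious members; link infections carry a single infector.
.simulateSimplicialCore <- function(pre, params, seedIdx) {
  betaL <- params@betaLink
  betaT <- params@betaTriad
  muI <- params@muI
  N <- pre$N
  sus <- rep(TRUE, N)
  inf <- rep(FALSE, N)
  recTime <- rep(Inf, N)
  recFinal <- rep(NA_real_, N)
  sus[seedIdx] <- FALSE
  inf[seedIdx] <- TRUE
  recTime[seedIdx] <- stats::rexp(length(seedIdx), muI)
  evTime <- numeric(); evTgt <- integer(); evSrc <- integer()
  evFrac <- numeric(); evMech <- character()
  stgNode <- seedIdx; stgName <- rep("I", length(seedIdx))
  stgTime <- rep(0, length(seedIdx))
  t <- 0

  while (any(inf)) {
    h <- numeric(N)
    if (betaL > 0) {
      a <- which(sus[pre$ei] & inf[pre$ej])
      if (length(a)) h <- h + .accum(N, pre$ei[a], betaL * pre$ew[a])
      b <- which(sus[pre$ej] & inf[pre$ei])
      if (length(b)) h <- h + .accum(N, pre$ej[b], betaL * pre$ew[b])
    }
    if (betaT > 0 && length(pre$ti)) {
      a <- which(sus[pre$ti] & inf[pre$tj] & inf[pre$tk])
      if (length(a)) h <- h + .accum(N, pre$ti[a], betaT * pre$tww[a])
      b <- which(sus[pre$tj] & inf[pre$ti] & inf[pre$tk])
      if (length(b)) h <- h + .accum(N, pre$tj[b], betaT * pre$tww[b])
      d <- which(sus[pre$tk] & inf[pre$ti] & inf[pre$tj])
      if (length(d)) h <- h + .accum(N, pre$tk[d], betaT * pre$tww[d])
    }
    lam <- sum(h)
    tRec <- min(recTime)
    tInf <- if (lam > 0) t + stats::rexp(1L, lam) else Inf
    if (tInf < tRec) {
      target <- sample.int(N, 1L, prob = h)
      # attribute the event: competing link and triad channels of the target
      lo <- pre$eOther[[target]]
      lw <- pre$eW[[target]]
      actL <- inf[lo]
      linkSrc <- lo[actL]
      linkRate <- betaL * lw[actL]
      t1 <- pre$tOther1[[target]]
      t2 <- pre$tOther2[[target]]
      twt <- pre$tW[[target]]
      actT <- inf[t1] & inf[t2]
      triRate <- betaT * twt[actT]
      rates <- c(linkRate, triRate)
      pick <- if (length(rates) == 1L) 1L
              else sample.int(length(rates), 1L, prob = rates)
      if (pick <= length(linkRate)) {
        evTime <- c(evTime, tInf); evTgt <- c(evTgt, target)
        evSrc <- c(evSrc, linkSrc[pick]); evFrac <- c(evFrac, 1)
        evMech <- c(evMech, "link")
      } else {
        kk <- pick - length(linkRate)
        pair <- c(t1[actT][kk], t2[actT][kk])
        evTime <- c(evTime, tInf, tInf); evTgt <- c(evTgt, target, target)
        evSrc <- c(evSrc, pair); evFrac <- c(evFrac, 0.5, 0.5)
        evMech <- c(evMech, "triad", "triad")
      }
      sus[target] <- FALSE
      inf[target] <- TRUE
      recTime[target] <- tInf + stats::rexp(1L, muI)
      stgNode <- c(stgNode, target); stgName <- c(stgName, "I")
      stgTime <- c(stgTime, tInf)
      t <- tInf
    } else {
      node <- which.min(recTime)
      inf[node] <- FALSE
      recFinal[node] <- tRec
      recTime[node] <- Inf
      stgNode <- c(stgNode, node); stgName <- c(stgName, "R")
      stgTime <- c(stgTime, tRec)
      t <- tRec
    }
  }

  infected <- which(!sus)
  list(evTime = evTime, evTgt = evTgt, evSrc = evSrc, evFrac = evFrac,
       evMech = evMech, stgNode = stgNode, stgName = stgName,
       stgTime = stgTime, seed = seedIdx[1L], nInfected = length(infected),
       attackRate = length(infected) / N,
       endTime = if (length(infected)) max(recFinal[infected]) else 0,
       seedRecovery = recFinal[seedIdx[1L]])
}

.thresholdPrep <- function(graph) {
  N <- length(graph@nodes)
  ed <- graph@edges
  W <- Matrix::sparseMatrix(i = c(ed$i, ed$j), j = c(ed$j, ed$i),
                            x = c(ed$W, ed$W), dims = c(N, N))
  list(N = N, W = W, tot = Matrix::rowSums(W))
}

# synchronous weighted threshold SIR. Infection decisions in a step use the
# infectious set at the start of the step: a susceptible node whose
# infectious-weight fraction strictly exceeds theta becomes infected, with
# attribution across the currently infectious neighbours proportional to
# the link weights. Each node's infectious duration (in steps) is pre-drawn
# as 1 + Geometric(1 - exp(-muI * dt)), i.e. recovery is checked after each
# full step the node spent infectious; pre-drawing couples realizations
# across theta for a fixed seed.
.simulateThresholdCore <- function(pre, params, seedIdx) {
  theta <- params@theta
  dt <- params@dt
  N <- pre$N
  W <- pre$W
  tot <- pre$tot
  p <- 1 - exp(-params@muI * dt)
  dur <- 1L + stats::rgeom(N, p)
  sus <- rep(TRUE, N)
  infectious <- rep(FALSE, N)
  remaining <- integer(N)
  sus[seedIdx] <- FALSE
  infectious[seedIdx] <- TRUE
  remaining[seedIdx] <- dur[seedIdx]
  evTime <- numeric(); evTgt <- integer(); evSrc <- integer()
  evFrac <- numeric(); evMech <- character()
  stgNode <- seedIdx; stgName <- rep("I", length(seedIdx))
  stgTime <- rep(0, length(seedIdx))
  step <- 0L
  endTime <- 0

  while (any(infectious)) {
    step <- step + 1L
    tNow <- step * dt
    infVec <- as.numeric(infectious)
    expo <- as.vector(W %*% infVec)
    frac <- ifelse(tot > 0, expo / tot, 0)
    newly <- which(sus & frac > theta)
    for (node in newly) {
      wrow <- W[node, ]
      srcs <- which(infectious & wrow > 0)
      wsum <- sum(wrow[srcs])
      evTime <- c(evTime, rep(tNow, length(srcs)))
      evTgt <- c(evTgt, rep.int(node, length(srcs)))
      evSrc <- c(evSrc, srcs)
      evFrac <- c(evFrac, wrow[srcs] / wsum)
      evMech <- c(evMech, rep("threshold", length(srcs)))
    }
    # recovery phase for nodes infectious at the start of the step
    active <- which(infectious)
    remaining[active] <- remaining[active] - 1L
    recovered <- active[remaining[active] == 0L]
    if (length(recovered)) {
      infectious[recovered] <- FALSE
      stgNode <- c(stgNode, recovered)
      stgName <- c(stgName, rep("R", length(recovered)))
      stgTime <- c(stgTime, rep(tNow, length(recovered)))
      endTime <- tNow
    }
    if (length(newly)) {
      sus[newly] <- FALSE
      infectious[newly] <- TRUE
      remaining[newly] <- dur[newly]
      stgNode <- c(stgNode, newly)
      stgName <- c(stgName, rep("I", length(newly)))
      stgTime <- c(stgTime, rep(tNow, length(newly)))
    }
  }

  infected <- which(!sus)
  list(evTime = evTime, evTgt = evTgt, evSrc = evSrc, evFrac = evFrac,
       evMech = evMech, stgNode = stgNode, stgName = stgName,
       stgTime = stgTime, seed = seedIdx[1L], nInfected = length(infected),
       attackRate = length(infected) / N, endTime = endTime,
       seedRecovery = NA_real_)
}

#' Simulate the simplicial contagion model on a weighted hypergraph
#'
#' SIR dynamics with two infection channels: pairwise (rate betaLink *
#' W[ij] per infectious neighbour) and triadic (rate betaTriad * W[ikl] per
#' triad whose two other members are both infectious). Triadic infections
#' split the attribution 1/2 + 1/2 between the two infectious members, who
#' play an equivalent role in the group contagion event regardless of their
#' individual link weights to the target.
#'
#' @param hg a \linkS4class{WeightedHypergraph}.
#' @param params a \linkS4class{SimplicialParams} object (or use the
#'   \code{simplicialParams} constructor).
#' @param seedNode seed specification (see \code{\link{runSimulations}}).
#' @param rngSeed integer seed.
#' @return a \linkS4class{ContagionRuns} object holding one run.
#' @export
simulateSimplicial <- function(hg, params, seedNode = "random", rngSeed) {
  stopifnot(is(params, "SimplicialParams"))
  runSimulations(hg, params, nRuns = 1L, rngSeed = rngSeed,
                 seedNode = seedNode)
}

#' Simulate the weighted threshold contagion model
#'
#' Synchronous discrete-time SIR in which a susceptible node becomes
#' infected (deterministically) when the weight of its connections to
#' currently infectious nodes divided by the total weight of all its
#' connections strictly exceeds theta. The denominator is static (all
#' neighbours, whatever their state); only currently infectious neighbours
#' count in the numerator. Attribution is proportional to the link weights
#' of the infectious neighbours. Isolated nodes are never infected.
#'
#' @param graph a \linkS4class{WeightedContactGraph}.
#' @param params a \linkS4class{ThresholdParams} object (or use the
#'   \code{thresholdParams} constructor).
#' @param seedNode seed specification (see \code{\link{runSimulations}}).
#' @param rngSeed integer seed.
#' @return a \linkS4class{ContagionRuns} object holding one run.
#' @export
simulateThreshold <- function(graph, params, seedNode = "random", rngSeed) {
  stopifnot(is(params, "ThresholdParams"))
  runSimulations(graph, params, nRuns = 1L, rngSeed = rngSeed,
                 seedNode = seedNode)
}
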