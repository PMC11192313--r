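#' SchoolLikeSpec: parameters of the synthetic contact generator
#'
#' Describes a school-like population: \code{nGroups} groups (classes) of
#' \code{groupSize} nodes observed over \code{nSnapshots} time slices.
#' Within-group and between-group pairs are independently active per
#' snapshot with heterogeneous (log-normally modulated) probabilities
#' centred on \code{pWithin} and \code{pBetween}, producing modular
#' structure and heavy-tailed contact counts. In addition, each group holds
#' a gathering (a simultaneous triangle of three members, emitted as the
#' three pair records at one timestamp) with probability \code{pGather} per
#' snapshot, so the hypergraph built from the events contains triads.
#'
#' \code{weightCorrelation} in [0, 1] controls the empirical coupling
#' between link and triad weights: gatherings recur on a small persistent
#' pool of triples with that probability (so frequently gathering triples
#' also accumulate pairwise counts, giving the positive link/triad weight
#' correlation seen in face-to-face data) and pick a uniformly random
#' triple otherwise.
#'
#' @slot nGroups,groupSize,nSnapshots population and observation sizes.
#' @slot pWithin,pBetween,pGather per-snapshot activation probabilities.
#' @slot weightCorrelation persistent-gathering probability in [0, 1].
#' @slot activitySigma sd of the log-normal per-pair activity modulation.
#' @slot poolSize number of persistent gathering triples per group.
#' @slot resolution seconds per snapshot.
#' @slot rngSeed integer seed.
#' @exportClass SchoolLikeSpec
setClass("SchoolLikeSpec",
  representation(nGroups = "integer", groupSize = "integer",
                 nSnapshots = "integer", pWithin = "numeric",
                 pBetween = "numeric", pGather = "numeric",
                 weightCorrelation = "numeric", activitySigma = "numeric",
                 poolSize = "integer", resolution = "numeric",
                 rngSeed = "integer"))

setValidity("SchoolLikeSpec", function(object) {
  pr <- c(object@pWithin, object@pBetween, object@pGather,
          object@weightCorrelation)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@nGroups * object@groupSize < 3L)
    return("population must have at least 3 nodes")
  if (object@groupSize < 3L && object@pGather > 0)
    return("gatherings need groups of size >= 3")
  if (object@nSnapshots < 1L) return("nSnapshots must be >= 1")
  TRUE
})

#' Construct a SchoolLikeSpec
#'
#' Defaults emulate a primary-school population: 10 groups of 24 nodes over
#' 3000 snapshots (roughly two school days at 20-second resolution), with
#' within-group contacts far more likely than between-group ones and a few
#' gatherings per group per day, with fully correlated link/triad weights.
#'
#' @param nGroups,groupSize,nSnapshots,pWithin,pBetween,pGather,resolution
#'   see \linkS4class{SchoolLikeSpec}.
#' @param weightCorrelation,activitySigma,poolSize see
#'   \linkS4class{SchoolLikeSpec}.
#' @param rngSeed integer seed.
#' @return a \linkS4class{SchoolLikeSpec}.
#' @export
schoolLikeSpec <- function(nGroups = 10, groupSize = 24, nSnapshots = 3000,
                           pWithin = 0.004, pBetween = 5e-5,
                           pGather = 0.02, weightCorrelation = 1,
                           activitySigma = 1, poolSize = 5, resolution = 20,
                           rngSeed = 1) {
  new("SchoolLikeSpec", nGroups = as.integer(nGroups),
      groupSize = as.integer(groupSize), nSnapshots = as.integer(nSnapshots),
      pWithin = pWithin, pBetween = pBetween, pGather = pGather,
      weightCorrelation = weightCorrelation, activitySigma = activitySigma,
      poolSize = as.integer(poolSize), resolution = resolution,
      rngSeed = as.integer(rngSeed))
}

# sample, for each pair, the snapshots in which it is active: counts are
# binomial per pair with a log-normal (mean-one) activity multiplier
.samplePairEvents <- function(pairs, nSnap, p, sigma) {
  if (p <= 0 || nrow(pairs) == 0)
    return(list(t = integer(), i = character(), j = character()))
  act <- exp(stats::rnorm(nrow(pairs), -sigma^2 / 2, sigma))
  pe <- pmin(1, p * act)
  cnt <- stats::rbinom(nrow(pairs), nSnap, pe)
  idx <- which(cnt > 0)
  snaps <- lapply(idx, function(k) sample.int(nSnap, cnt[k]))
  list(t = unlist(snaps, use.names = FALSE),
       i = rep(pairs$i[idx], cnt[idx]),
       j = rep(pairs$j[idx], cnt[idx]))
}

#' Generate a synthetic school-like contact event list
#'
#' @param spec a \linkS4class{SchoolLikeSpec}.
#' @return a \linkS4class{ContactEvents} object; byte-identical for equal
#'   specs (the seed lives in the spec).
#' @export
generateSchoolLikeEvents <- function(spec) {
  stopifnot(is(spec, "SchoolLikeSpec"))
  set.seed(spec@rngSeed)
  ng <- spec@nGroups
  gs <- spec@groupSize
  nSnap <- spec@nSnapshots
  nodes <- as.vector(vapply(seq_len(ng), function(g)
    sprintf("g%02dn%02d", g, seq_len(gs)), character(gs)))
  group <- rep(seq_len(ng), each = gs)

  withinPairs <- do.call(rbind, lapply(seq_len(ng), function(g) {
    m <- nodes[group == g]
    cb <- utils::combn(m, 2L)
    data.frame(i = cb[1L, ], j = cb[2L, ])
  }))
  allPairs <- utils::combn(nodes, 2L)
  between <- group[match(allPairs[1L, ], nodes)] !=
    group[match(allPairs[2L, ], nodes)]
  betweenPairs <- data.frame(i = allPairs[1L, between],
                             j = allPairs[2L, between])

  wEv <- .samplePairEvents(withinPairs, nSnap, spec@pWithin,
                           spec@activitySigma)
  bEv <- .samplePairEvents(betweenPairs, nSnap, spec@pBetween,
                           spec@activitySigma)

  gt <- integer(); gi <- character(); gj <- character()
  if (spec@pGather > 0) {
    # persistent gathering pools: a few triples per group, with decreasing
    # popularity, reused with probability weightCorrelation
    for (g in seq_len(ng)) {
      m <- nodes[group == g]
      pool <- lapply(seq_len(spec@poolSize), function(dummy) sort(sample(m, 3L)))
      poolW <- 2^(-(seq_len(spec@poolSize) - 1L))
      cnt <- stats::rbinom(1L, nSnap, spec@pGather)
      if (cnt == 0L) next
      snaps <- sample.int(nSnap, cnt)
      for (s in snaps) {
        tri <- if (stats::runif(1L) < spec@weightCorrelation)
          pool[[sample.int(spec@poolSize, 1L, prob = poolW)]]
        else sort(sample(m, 3L))
        gt <- c(gt, rep(s, 3L))
        gi <- c(gi, tri[c(1L, 1L, 2L)])
        gj <- c(gj, tri[c(2L, 3L, 3L)])
      }
    }
  }

  t <- c(wEv$t, bEv$t, gt)
  if (!length(t)) stop("no contacts generated: degenerate spec")
  contactEventList(t = t * spec@resolution,
                   i = c(wEv$i, bEv$i, gi),
                   j = c(wEv$j, bEv$j, gj),
                   resolution = spec@resolution)
}

#' Deterministic toy contact graphs
#'
#' Small analytically tractable fixtures: \code{"two_node"} (one edge),
#' \code{"star"} (a hub and size - 1 leaves), \code{"chain"} (a path), and
#' \code{"hub_triangle"} (a fixed 7-node network with heterogeneous weights, a
#' hub and a triangle, on which the infection pattern is visibly
#' asymmetric). Weights must be pre-normalized (maximum 1); raw counts are
#' nominal (n = W, n_max = 1).
#'
#' @param kind one of "two_node", "star", "chain", "hub_triangle".
#' @param size number of nodes (ignored for hub_triangle).
#' @param weights edge weights along the construction order (two_node: 1
#'   weight; star: size - 1 leaf weights; chain: size - 1 path weights);
#'   default all 1.
#' @return a \linkS4class{WeightedContactGraph}.
#' @export
makeToyGraph <- function(kind = c("two_node", "star", "chain", "hub_triangle"),
                         size = 2, weights = NULL) {
  kind <- match.arg(kind)
  mk <- function(nodes, i, j, W) {
    new("WeightedContactGraph", nodes = nodes,
        edges = data.frame(i = i, j = j, n = W, W = W), nMax = 1)
  }
  if (kind == "two_node") {
    if (size != 2) stop("two_node graphs have size 2")
    W <- if (is.null(weights)) 1 else weights
    mk(c("a", "b"), 1L, 2L, W)
  } else if (kind == "star") {
    if (size < 2) stop("a star needs at least 2 nodes")
    W <- if (is.null(weights)) rep(1, size - 1) else weights
    stopifnot(length(W) == size - 1)
    mk(c("hub", paste0("leaf", seq_len(size - 1))),
       rep(1L, size - 1L), seq(2L, size), W)
  } else if (kind == "chain") {
    if (size < 2) stop("a chain needs at least 2 nodes")
    W <- if (is.null(weights)) rep(1, size - 1) else weights
    stopifnot(length(W) == size - 1)
    nm <- if (size <= 26) letters[seq_len(size)] else
      paste0("n", seq_len(size))
    mk(nm, seq_len(size - 1L), seq(2L, size), W)
  } else {
    ii <- c(1L, 1L, 1L, 2L, 2L, 4L, 5L, 6L)
    jj <- c(2L, 3L, 4L, 3L, 7L, 5L, 6L, 7L)
    W <- c(1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
    mk(paste0("n", 1:7), ii, jj, W)
  }
}
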