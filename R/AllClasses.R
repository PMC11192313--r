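#' @import methods
#' @importFrom Matrix sparseMatrix
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

#' ContactEvents: time-resolved pairwise contact records
#'
#' Ordered records (t, i, j) of pairwise interaction slices at a fixed
#' temporal resolution (20 s in the SocioPatterns datasets this format comes
#' from). Records are stored time-sorted, with the two node ids of each pair
#' canonicalized (i < j lexicographically), deduplicated on (t, \{i, j\}), and
#' with self-contacts dropped at construction.
#'
#' @slot events data.frame with integer column \code{t} and character columns
#'   \code{i}, \code{j}.
#' @slot resolution seconds per interaction slice.
#' @slot nDropped number of self-contact records dropped while building.
#' @exportClass ContactEvents
setClass("ContactEvents",
  representation(events = "data.frame", resolution = "numeric",
                 nDropped = "integer"),
  prototype(events = data.frame(t = integer(), i = character(),
                                j = character()),
            resolution = 20, nDropped = 0L))

setValidity("ContactEvents", function(object) {
  ev <- object@events
  if (!all(c("t", "i", "j") %in% names(ev)))
    return("events must have columns t, i, j")
  if (nrow(ev)) {
    if (any(ev$i == ev$j)) return("self-contacts (i == j) are not allowed")
    if (is.unsorted(ev$t)) return("records must be sorted by t")
    if (anyDuplicated(paste(ev$t, ev$i, ev$j)))
      return("(t, i, j) records must be unique")
    if (any(ev$i > ev$j)) return("pair ids must be canonicalized (i < j)")
  }
  if (object@resolution <= 0) return("resolution must be positive")
  TRUE
})

#' WeightedContactGraph: time-aggregated weighted contact network
#'
#' Undirected weighted graph in which the raw weight n[ij] counts the number
#' of interaction slices of the pair (i, j), and the normalized weight
#' W[ij] = n[ij] / n_max lies in (0, 1] with max W = 1 exactly.
#'
#' @slot nodes character vector of node ids; the position of an id is its
#'   stable integer index, used by every matrix in the package.
#' @slot edges data.frame with integer index columns \code{i} < \code{j},
#'   raw count \code{n} and normalized weight \code{W}.
#' @slot nMax the maximal raw pair count used for normalization.
#' @exportClass WeightedContactGraph
setClass("WeightedContactGraph",
  representation(nodes = "character", edges = "data.frame", nMax = "numeric"))

setValidity("WeightedContactGraph", function(object) {
  ed <- object@edges
  if (!all(c("i", "j", "n", "W") %in% names(ed)))
    return("edges must have columns i, j, n, W")
  if (nrow(ed) == 0) return("graph must have at least one edge")
  N <- length(object@nodes)
  if (any(ed$i < 1L | ed$j > N)) return("edge endpoints out of range")
  if (any(ed$i >= ed$j)) return("edges must satisfy i < j (no self-loops)")
  if (anyDuplicated(ed$i + N * ed$j)) return("duplicate edges")
  if (any(ed$W <= 0 | ed$W > 1)) return("weights must lie in (0, 1]")
  if (abs(max(ed$W) - 1) > 1e-12) return("maximal weight must be exactly 1")
  TRUE
})

#' WeightedHypergraph: contact network plus weighted triads
#'
#' A \linkS4class{WeightedContactGraph} augmented with hyperedges of size 3
#' (triads), obtained by enumerating cliques of simultaneous interactions in
#' each temporal snapshot. The triad weight is n[ijk] / n2max where n[ijk]
#' counts the snapshots containing the triad and n2max is the maximum of
#' those counts.
#'
#' @slot graph the base \linkS4class{WeightedContactGraph}.
#' @slot triads data.frame with sorted integer index columns \code{i} <
#'   \code{j} < \code{k}, raw count \code{n} and normalized weight \code{W}.
#' @slot nMaxTriad the maximal raw triad count used for normalization.
#' @exportClass WeightedHypergraph
setClass("WeightedHypergraph",
  representation(graph = "WeightedContactGraph", triads = "data.frame",
                 nMaxTriad = "numeric"))

setValidity("WeightedHypergraph", function(object) {
  tr <- object@triads
  if (!all(c("i", "j", "k", "n", "W") %in% names(tr)))
    return("triads must have columns i, j, k, n, W")
  if (nrow(tr)) {
    if (any(tr$i >= tr$j | tr$j >= tr$k))
      return("triads must satisfy i < j < k")
    if (any(tr$W <= 0 | tr$W > 1)) return("triad weights must lie in (0, 1]")
    if (abs(max(tr$W) - 1) > 1e-12)
      return("maximal triad weight must be exactly 1")
    # triad closure: every constituent pair must be an edge of the base graph
    ed <- object@graph@edges
    N <- length(object@graph@nodes)
    key <- function(a, b) a + N * b
    ekeys <- key(ed$i, ed$j)
    pkeys <- c(key(tr$i, tr$j), key(tr$i, tr$k), key(tr$j, tr$k))
    if (!all(pkeys %in% ekeys))
      return("every triad's three pairs must be edges of the base graph")
  }
  TRUE
})

#' ContagionRuns: event logs and summaries of stochastic epidemic runs
#'
#' Holds one or more stochastic realizations of a contagion process on a
#' common substrate: every infection event with its timestamp, infectee,
#' mechanism and fractional attribution to infectors, per-node stage entry
#' times, and per-run summaries (seed, final attack rate, end time).
#'
#' Attribution is fractional for complex contagion: a triadic infection by a
#' pair of infectious nodes is split 1/2 + 1/2 between them, and a threshold
#' infection is split across the infectious neighbours proportionally to the
#' link weights. The fractions of each infection event sum to exactly 1, so
#' the number of infection events equals the total attributed mass.
#'
#' @slot events data.frame with columns \code{run}, \code{time},
#'   \code{infectee}, \code{infector} (integer node indices), \code{fraction}
#'   and \code{mechanism} (one of "link", "triad", "threshold"); one row per
#'   (event, infector) pair.
#' @slot summaries data.frame with columns \code{run}, \code{seed},
#'   \code{attackRate} and \code{endTime}.
#' @slot stages data.frame with columns \code{run}, \code{node}, \code{stage}
#'   and \code{time} (stage entry times).
#' @slot nodes character vector of node ids shared with the substrate.
#' @slot model character label of the generating model.
#' @slot nRuns number of runs, including runs without any infection event.
#' @exportClass ContagionRuns
setClass("ContagionRuns",
  representation(events = "data.frame", summaries = "data.frame",
                 stages = "data.frame", nodes = "character",
                 model = "character", nRuns = "integer"))

setValidity("ContagionRuns", function(object) {
  ev <- object@events
  sm <- object@summaries
  if (nrow(sm) != object@nRuns) return("one summary row per run required")
  N <- length(object@nodes)
  if (nrow(ev)) {
    if (any(ev$fraction <= 0 | ev$fraction > 1))
      return("attribution fractions must lie in (0, 1]")
    if (any(ev$infectee < 1L | ev$infectee > N))
      return("infectee index out of range")
    # each node infected at most once per run; the seed never as infectee
    evkey <- paste(ev$run, ev$infectee)
    one <- !duplicated(evkey)
    tot <- tapply(ev$fraction, evkey, sum)
    if (any(abs(tot - 1) > 1e-9))
      return("fractions of each infection event must sum to 1")
    seeds <- sm$seed[match(ev$run, sm$run)]
    if (any(ev$infectee == seeds))
      return("a seed node cannot appear as infectee")
  }
  if (any(sm$attackRate < 0 | sm$attackRate > 1))
    return("attack rates must lie in [0, 1]")
  TRUE
})

#' InfectionPattern: who-infected-whom probability matrix
#'
#' Directed non-negative matrix C in which C[i, j] is the probability,
#' averaged over runs, that node i directly infected node j: the summed
#' attributed fractions of all infection events from i to j (optionally
#' restricted to events up to a time cutoff and/or to one mechanism),
#' divided by the number of runs.
#'
#' @slot C sparse non-negative matrix (\code{dgCMatrix}) over node indices.
#' @slot nRuns number of runs averaged (runs without events included).
#' @slot timeCutoff events after this time were excluded (\code{Inf}: none).
#' @slot mechanismFilter "all" or the mechanism retained.
#' @slot nodes character vector of node ids indexing rows and columns.
#' @exportClass InfectionPattern
setClass("InfectionPattern",
  representation(C = "dgCMatrix", nRuns = "integer", timeCutoff = "numeric",
                 mechanismFilter = "character", nodes = "character"))

setValidity("InfectionPattern", function(object) {
  C <- object@C
  N <- length(object@nodes)
  if (nrow(C) != N || ncol(C) != N)
    return("C must be square over the node index")
  if (any(C@x < 0)) return("C must be non-negative")
  if (any(C@x > 1 + 1e-9)) return("no entry of C can exceed 1")
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  TRUE
})
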