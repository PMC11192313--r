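#' Accessors for the package's S4 containers
#'
#' @param x an object of one of the package's S4 classes.
#' @return \code{contactEvents}: the record data.frame; \code{graphNodes}:
#'   the character vector of node ids; \code{graphEdges}, \code{triads}:
#'   data.frames of weighted (hyper)edges; \code{runEvents},
#'   \code{runSummaries}, \code{stageHistory}: run-log data.frames;
#'   \code{patternMatrix}: the sparse C matrix; \code{nRuns}: run count.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contactEvents", function(x) standardGeneric("contactEvents"))
#' @rdname accessors
#' @export
setMethod("contactEvents", "ContactEvents", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setMethod("graphNodes", "WeightedContactGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphNodes", "WeightedHypergraph", function(x) x@graph@nodes)
#' @rdname accessors
#' @export
setMethod("graphNodes", "ContagionRuns", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphNodes", "InfectionPattern", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "WeightedContactGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("graphEdges", "WeightedHypergraph", function(x) x@graph@edges)

#' @rdname accessors
#' @export
setGeneric("baseGraph", function(x) standardGeneric("baseGraph"))
#' @rdname accessors
#' @export
setMethod("baseGraph", "WeightedHypergraph", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("triads", function(x) standardGeneric("triads"))
#' @rdname accessors
#' @export
setMethod("triads", "WeightedHypergraph", function(x) x@triads)

#' @rdname accessors
#' @export
setGeneric("runEvents", function(x) standardGeneric("runEvents"))
#' @rdname accessors
#' @export
setMethod("runEvents", "ContagionRuns", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("runSummaries", function(x) standardGeneric("runSummaries"))
#' @rdname accessors
#' @export
setMethod("runSummaries", "ContagionRuns", function(x) x@summaries)

#' @rdname accessors
#' @export
setGeneric("stageHistory", function(x) standardGeneric("stageHistory"))
#' @rdname accessors
#' @export
setMethod("stageHistory", "ContagionRuns", function(x) x@stages)

#' @rdname accessors
#' @export
setGeneric("patternMatrix", function(x) standardGeneric("patternMatrix"))
#' @rdname accessors
#' @export
setMethod("patternMatrix", "InfectionPattern", function(x) x@C)

#' @rdname accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))
#' @rdname accessors
#' @export
setMethod("nRuns", "ContagionRuns", function(x) x@nRuns)
#' @rdname accessors
#' @export
setMethod("nRuns", "InfectionPattern", function(x) x@nRuns)

setMethod("show", "ContactEvents", function(object) {
  ev <- object@events
  cat("ContactEvents:", nrow(ev), "records,",
      length(unique(c(ev$i, ev$j))), "nodes, resolution",
      object@resolution, "s\n")
  if (nrow(ev))
    cat("  time span:", min(ev$t), "-", max(ev$t), "s;",
        object@nDropped, "self-contacts dropped\n")
})

setMethod("show", "WeightedContactGraph", function(object) {
  cat("WeightedContactGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges, n_max =", object@nMax, "\n")
})

setMethod("show", "WeightedHypergraph", function(object) {
  cat("WeightedHypergraph:", length(object@graph@nodes), "nodes,",
      nrow(object@graph@edges), "edges,", nrow(object@triads),
      "triads, n2_max =", object@nMaxTriad, "\n")
})

setMethod("show", "ContagionRuns", function(object) {
  cat("ContagionRuns:", object@nRuns, "run(s) of", object@model, "on",
      length(object@nodes), "nodes\n")
  if (object@nRuns)
    cat("  mean attack rate:",
        signif(mean(object@summaries$attackRate), 4), "\n")
})

setMethod("show", "InfectionPattern", function(object) {
  cat("InfectionPattern over", length(object@nodes), "nodes (",
      length(object@C@x), "non-zero entries ), averaged over",
      object@nRuns, "runs\n")
  cat("  sum(C) =", signif(sum(object@C), 5), "; time cutoff",
      object@timeCutoff, "; mechanism filter", object@mechanismFilter, "\n")
})
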