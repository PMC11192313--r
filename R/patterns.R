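#' Build an infection pattern matrix C from simulation runs
#'
#' C[i, j] is the summed attributed fraction of all infection events from i
#' to j across runs, divided by the number of runs: the probability that i
#' directly infected j, averaged over realizations. Runs without any
#' infection event still count in the denominator. Events can be restricted
#' to those occurring up to \code{timeCutoff} and/or to one mechanism
#' ("link", "triad", "threshold"), which yields the mechanism decomposition
#' C1 + C2 = C of the simplicial model.
#'
#' @param runs a \linkS4class{ContagionRuns} object (>= 1 run).
#' @param timeCutoff keep events with time <= cutoff (default Inf).
#' @param mechanismFilter "all" or a mechanism label.
#' @return an \linkS4class{InfectionPattern}.
#' @export
buildInfectionPattern <- function(runs, timeCutoff = Inf,
                                  mechanismFilter = "all") {
  stopifnot(is(runs, "ContagionRuns"))
  if (runs@nRuns < 1L) stop("at least one run required")
  ev <- runs@events
  if (!identical(mechanismFilter, "all"))
    ev <- ev[ev$mechanism %in% mechanismFilter, , drop = FALSE]
  ev <- ev[ev$time <= timeCutoff, , drop = FALSE]
  N <- length(runs@nodes)
  C <- Matrix::sparseMatrix(i = ev$infector, j = ev$infectee,
                            x = ev$fraction / runs@nRuns, dims = c(N, N),
                            repr = "C")
  p <- new("InfectionPattern")
  p@C <- C
  p@nRuns <- runs@nRuns
  p@timeCutoff <- timeCutoff
  p@mechanismFilter <- paste(mechanismFilter, collapse = "+")
  p@nodes <- runs@nodes
  validObject(p)
  p
}

#' Time-resolved infection patterns C(t) on a time grid
#'
#' One pattern per grid time, each built from the contagion events occurring
#' up to that time; entries are entrywise non-decreasing along the grid.
#'
#' @param runs a \linkS4class{ContagionRuns} object.
#' @param timeGrid sorted ascending vector of cutoff times.
#' @param mechanismFilter "all" or a mechanism label.
#' @return list of \linkS4class{InfectionPattern} objects, named by grid
#'   time.
#' @export
timePatternCurve <- function(runs, timeGrid, mechanismFilter = "all") {
  if (is.unsorted(timeGrid)) stop("timeGrid must be sorted ascending")
  out <- lapply(timeGrid, function(tc)
    buildInfectionPattern(runs, timeCutoff = tc,
                          mechanismFilter = mechanismFilter))
  names(out) <- as.character(timeGrid)
  out
}

#' Spreader and receiver indices of an infection pattern
#'
#' The spreader index s[i] (row sum of C) quantifies a node's tendency to
#' contaminate its neighbours; the receiver index r[i] (column sum)
#' quantifies its risk of being contaminated. r[i] equals the fraction of
#' runs in which node i was infected as a non-seed, hence r[i] <= 1.
#'
#' @param p an \linkS4class{InfectionPattern}.
#' @return data.frame with columns \code{node}, \code{spreader},
#'   \code{receiver}.
#' @export
nodeIndices <- function(p) {
  stopifnot(is(p, "InfectionPattern"))
  data.frame(node = p@nodes,
             spreader = Matrix::rowSums(p@C),
             receiver = Matrix::colSums(p@C))
}

#' Keep only runs whose final attack rate falls in a closed window
#'
#' Used to condition infection patterns on the final epidemic size, e.g.
#' comparing processes at different R0 restricted to runs with attack rate
#' in [0.75, 0.85].
#'
#' @param runs a \linkS4class{ContagionRuns} object.
#' @param lo,hi closed window bounds, 0 <= lo < hi <= 1.
#' @return a \linkS4class{ContagionRuns} with the kept runs (renumbered) and
#'   the kept count attached as attribute \code{"kept"}.
#' @export
filterRunsByAttackRate <- function(runs, lo, hi) {
  stopifnot(is(runs, "ContagionRuns"), lo >= 0, hi <= 1, lo < hi)
  keep <- which(runs@summaries$attackRate >= lo &
                runs@summaries$attackRate <= hi)
  out <- subsetRuns(runs, keep)
  attr(out, "kept") <- length(keep)
  out
}

#' Subset or concatenate ContagionRuns
#'
#' @param runs a \linkS4class{ContagionRuns} object.
#' @param which run numbers to keep (runs are renumbered 1..n).
#' @return a \linkS4class{ContagionRuns}.
#' @export
subsetRuns <- function(runs, which) {
  sm <- runs@summaries[match(which, runs@summaries$run), , drop = FALSE]
  remap <- function(df) {
    df <- df[df$run %in% which, , drop = FALSE]
    df$run <- match(df$run, which)
    df[order(df$run), , drop = FALSE]
  }
  ev <- remap(runs@events)
  st <- remap(runs@stages)
  sm$run <- seq_len(nrow(sm))
  rownames(ev) <- rownames(st) <- rownames(sm) <- NULL
  initialize(runs, events = ev, stages = st, summaries = sm,
             nRuns = as.integer(nrow(sm)))
}

#' @rdname subsetRuns
#' @param x,y two \linkS4class{ContagionRuns} objects on the same node set.
#' @export
bindRuns <- function(x, y) {
  stopifnot(identical(x@nodes, y@nodes))
  off <- x@nRuns
  ye <- y@events; ye$run <- ye$run + off
  ys <- y@stages; ys$run <- ys$run + off
  ysm <- y@summaries; ysm$run <- ysm$run + off
  initialize(x, events = rbind(x@events, ye),
             stages = rbind(x@stages, ys),
             summaries = rbind(x@summaries, ysm),
             nRuns = as.integer(off + y@nRuns))
}

#' Location of the non-zero mode of an attack-rate distribution
#'
#' Histograms the final attack rates on [0, 1] with the given bin width and
#' returns the centre of the most populated bin among those whose centre
#' exceeds \code{zeroCutoff}; attack-rate distributions of SIR-like
#' processes are typically bimodal, and this picks the epidemic mode while
#' ignoring the early-extinction peak near zero.
#'
#' @param attackRates numeric vector of final attack rates, or a
#'   \linkS4class{ContagionRuns} object.
#' @param binWidth histogram bin width (default 0.02).
#' @param zeroCutoff bins with centre <= cutoff are ignored (default 0.1).
#' @return the mode bin centre, or NA if no run exceeds the cutoff.
#' @export
attackRateMode <- function(attackRates, binWidth = 0.02, zeroCutoff = 0.1) {
  if (is(attackRates, "ContagionRuns"))
    attackRates <- attackRates@summaries$attackRate
  if (binWidth <= 0) stop("binWidth must be positive")
  if (!length(attackRates)) stop("no attack rates supplied")
  if (!any(attackRates > zeroCutoff)) return(NA_real_)
  breaks <- seq(0, 1 + binWidth, by = binWidth)
  bin <- findInterval(attackRates, breaks, rightmost.closed = FALSE)
  centers <- breaks[bin] + binWidth / 2
  counts <- table(centers)
  cc <- as.numeric(names(counts))
  ok <- cc > zeroCutoff
  if (!any(ok)) return(NA_real_)
  cc[ok][which.max(counts[ok])]
}

#' Per-run attack rate at a given time
#'
#' The fraction of nodes ever infected (seed included) by time \code{t} in
#' each run.
#'
#' @param runs a \linkS4class{ContagionRuns} object.
#' @param t time.
#' @return numeric vector, one value per run.
#' @export
attackRateAtTime <- function(runs, t) {
  ev <- runs@events
  ev <- ev[ev$time <= t & !duplicated(paste(ev$run, ev$infectee)), ,
           drop = FALSE]
  n <- tabulate(ev$run, nbins = runs@nRuns)
  # the seed counts even when no one else is infected yet
  (n + 1) / length(runs@nodes)
}

#' Export an infection pattern and node indices
#'
#' \code{writePattern} writes the non-zero entries as a TSV (i, j, C_ij);
#' \code{writeNodeIndices} writes a CSV (node, spreader, receiver).
#'
#' @param p an \linkS4class{InfectionPattern}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePattern <- function(p, path) {
  stopifnot(is(p, "InfectionPattern"))
  tm <- methods::as(p@C, "TsparseMatrix")
  out <- data.frame(i = p@nodes[tm@i + 1L], j = p@nodes[tm@j + 1L],
                    C_ij = tm@x)
  out <- out[order(out$i, out$j), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePattern
#' @export
writeNodeIndices <- function(p, path) {
  utils::write.csv(nodeIndices(p), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
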