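#' Build a ContactEvents object from raw records
#'
#' Canonicalizes pair order, drops self-contacts with a warning, removes
#' duplicated (t, \{i, j\}) records and sorts by time.
#'
#' @param t integer vector of timestamps (seconds).
#' @param i,j node ids (coerced to character).
#' @param resolution seconds per interaction slice (default 20, the
#'   SocioPatterns sampling interval).
#' @return a \linkS4class{ContactEvents} object.
#' @export
contactEventList <- function(t, i, j, resolution = 20) {
  i <- as.character(i); j <- as.character(j)
  t <- as.integer(t)
  stopifnot(length(t) == length(i), length(i) == length(j))
  self <- i == j
  nDropped <- sum(self)
  if (nDropped)
    warning(nDropped, " self-contact record(s) dropped")
  t <- t[!self]; i <- i[!self]; j <- j[!self]
  a <- pmin(i, j); b <- pmax(i, j)
  ord <- order(t, a, b)
  ev <- data.frame(t = t[ord], i = a[ord], j = b[ord],
                   stringsAsFactors = FALSE)
  ev <- ev[!duplicated(ev), , drop = FALSE]
  rownames(ev) <- NULL
  new("ContactEvents", events = ev, resolution = resolution,
      nDropped = as.integer(nDropped))
}

#' Read a SocioPatterns-style contact list
#'
#' Parses plain-text (optionally gzip-compressed) files with one interaction
#' record per line in the form \code{"t i j"}; extra metadata columns (such
#' as the class labels in the primary-school dataset) are ignored. Records
#' are deduplicated and time-sorted; self-contacts are dropped with a
#' warning.
#'
#' @param path file path; \code{.gz} suffix triggers transparent
#'   decompression.
#' @param resolution seconds per interaction slice (default 20).
#' @param sep field separator regular expression (default: any whitespace).
#' @return a \linkS4class{ContactEvents} object.
#' @export
readContactEvents <- function(path, resolution = 20, sep = "[ \t]+") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  fields <- strsplit(trimws(lines[keep]), sep)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed record at line ", lineNo[which(nf < 3)[1]],
         ": fewer than 3 fields")
  t <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  if (anyNA(t))
    stop("malformed record at line ", lineNo[which(is.na(t))[1]],
         ": first field is not an integer time")
  contactEventList(t,
                   vapply(fields, `[[`, "", 2L),
                   vapply(fields, `[[`, "", 3L),
                   resolution = resolution)
}

#' Write a ContactEvents object as a "t i j" TSV
#'
#' Emits the same dialect \code{\link{readContactEvents}} parses, so
#' synthetic data round-trips through the file interface.
#'
#' @param x a \linkS4class{ContactEvents} object.
#' @param path output path.
#' @export
writeContactEvents <- function(x, path) {
  stopifnot(is(x, "ContactEvents"))
  utils::write.table(x@events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregate contact events into a weighted contact graph
#'
#' Counts, for every unordered pair (i, j), the number n[ij] of interaction
#' slices in which the pair appears, and normalizes the link weights by the
#' maximal count: W[ij] = n[ij] / n_max, so the heaviest link has weight
#' exactly 1. Node ids become a stable integer index (sorted order of the
#' original ids).
#'
#' @param events a \linkS4class{ContactEvents} object.
#' @return a \linkS4class{WeightedContactGraph}.
#' @export
aggregateWeightedGraph <- function(events) {
  stopifnot(is(events, "ContactEvents"))
  ev <- events@events
  if (nrow(ev) == 0) stop("empty event list: no weights definable")
  nodes <- sort(unique(c(ev$i, ev$j)))
  ii <- match(ev$i, nodes)
  jj <- match(ev$j, nodes)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  key <- paste(a, b)
  tb <- table(key)
  n <- as.vector(tb)
  ab <- do.call(rbind, strsplit(names(tb), " "))
  nMax <- max(n)
  edges <- data.frame(i = as.integer(ab[, 1]), j = as.integer(ab[, 2]),
                      n = n, W = n / nMax)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new("WeightedContactGraph", nodes = nodes, edges = edges, nMax = nMax)
}

#' Build a weighted hypergraph (links + triads) from contact events
#'
#' For each timestamp the snapshot graph of simultaneous interactions is
#' built; its maximal cliques of size at least 3 are enumerated and each
#' clique of size m > 3 is decomposed into all choose(m, 3) triads. n[ijk]
#' counts the snapshots in which triad ijk appears (at most once per
#' snapshot, whatever the number of containing cliques); triad weights are
#' n[ijk] / n2max. The base graph is the time-aggregated weighted graph of
#' the same events, so every triad's three pairs exist as links.
#'
#' @param events a \linkS4class{ContactEvents} object.
#' @return a \linkS4class{WeightedHypergraph}.
#' @export
buildWeightedHypergraph <- function(events) {
  graph <- aggregateWeightedGraph(events)
  ev <- events@events
  nodes <- graph@nodes
  ii <- match(ev$i, nodes)
  jj <- match(ev$j, nodes)
  N <- length(nodes)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  bySnap <- split(seq_len(nrow(ev)), ev$t)
  for (rows in bySnap) {
    if (length(rows) < 3L) next  # a triangle needs >= 3 simultaneous edges
    g <- igraph::graph_from_edgelist(cbind(ii[rows], jj[rows]),
                                     directed = FALSE)
    cl <- igraph::max_cliques(g, min = 3L)
    if (!length(cl)) next
    seen <- character()
    for (clq in cl) {
      v <- sort(as.integer(clq))
      tri <- utils::combn(v, 3L)
      keys <- paste(tri[1L, ], tri[2L, ], tri[3L, ])
      seen <- c(seen, keys)
    }
    for (k in unique(seen)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    idx <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
    n <- vapply(keys, function(k) counts[[k]], integer(1L))
    n2max <- max(n)
    tr <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                     n = as.integer(n), W = n / n2max)
    tr <- tr[order(tr$i, tr$j, tr$k), , drop = FALSE]
    rownames(tr) <- NULL
  } else {
    tr <- data.frame(i = integer(), j = integer(), k = integer(),
                     n = integer(), W = numeric())
    n2max <- NA_real_
  }
  new("WeightedHypergraph", graph = graph, triads = tr, nMaxTriad = n2max)
}

#' Shuffle triad weights across the hyperedges of a hypergraph
#'
#' Randomly permutes the multiset of triad weights (and the raw counts they
#' derive from) over the existing triads, leaving link weights and triad
#' membership unchanged. This destroys the empirical positive correlation
#' between link and triad weights while preserving both marginals, the
#' decorrelated regime used to probe why simple and simplicial infection
#' patterns resemble each other.
#'
#' @param hg a \linkS4class{WeightedHypergraph} with at least 2 triads.
#' @param rngSeed integer seed making the permutation reproducible.
#' @return a \linkS4class{WeightedHypergraph} with permuted triad weights.
#' @export
shuffleTriadWeights <- function(hg, rngSeed) {
  stopifnot(is(hg, "WeightedHypergraph"))
  tr <- hg@triads
  if (nrow(tr) < 2L) stop("need at least 2 triads to shuffle")
  set.seed(as.integer(rngSeed))
  perm <- sample.int(nrow(tr))
  tr$n <- tr$n[perm]
  tr$W <- tr$W[perm]
  initialize(hg, triads = tr)
}

#' Export the weighted edge and triad lists
#'
#' @param x a \linkS4class{WeightedContactGraph} or
#'   \linkS4class{WeightedHypergraph}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  if (is(x, "WeightedHypergraph")) x <- x@graph
  stopifnot(is(x, "WeightedContactGraph"))
  ed <- x@edges
  out <- data.frame(i = x@nodes[ed$i], j = x@nodes[ed$j],
                    n_ij = ed$n, W_ij = ed$W)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeTriadList <- function(x, path) {
  stopifnot(is(x, "WeightedHypergraph"))
  tr <- x@triads
  nodes <- x@graph@nodes
  out <- data.frame(i = nodes[tr$i], j = nodes[tr$j], k = nodes[tr$k],
                    n_ijk = tr$n, W_ijk = tr$W)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
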