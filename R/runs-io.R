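#' Serialize and reload contagion run logs
#'
#' \code{writeRunEvents} writes one JSON object per infection event (fields
#' \code{run}, \code{t}, \code{infectee}, \code{mechanism} and an
#' \code{attribution} map from infector id to fraction) as JSON lines;
#' \code{writeRunSummaries} writes the per-run summaries as CSV;
#' \code{readContagionRuns} reloads both into a
#' \linkS4class{ContagionRuns} suitable for pattern building (stage
#' histories are not serialized).
#'
#' @param runs a \linkS4class{ContagionRuns} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRunEvents <- function(runs, path) {
  stopifnot(is(runs, "ContagionRuns"))
  ev <- runs@events
  con <- file(path, "wt")
  on.exit(close(con))
  if (nrow(ev)) {
    key <- paste(ev$run, ev$infectee)
    first <- !duplicated(key)
    for (k in which(first)) {
      rows <- which(key == key[k])
      attribution <- as.list(ev$fraction[rows])
      names(attribution) <- runs@nodes[ev$infector[rows]]
      writeLines(jsonlite::toJSON(list(
        run = ev$run[k], t = ev$time[k],
        infectee = runs@nodes[ev$infectee[k]],
        mechanism = ev$mechanism[k],
        attribution = attribution), auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname writeRunEvents
#' @export
writeRunSummaries <- function(runs, path) {
  stopifnot(is(runs, "ContagionRuns"))
  sm <- runs@summaries
  sm$seed <- runs@nodes[sm$seed]
  utils::write.csv(sm, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRunEvents
#' @param eventsPath JSON-lines file written by \code{writeRunEvents}.
#' @param summariesPath CSV file written by \code{writeRunSummaries}.
#' @param nodes character vector of node ids fixing the node index (must
#'   match the substrate the runs were simulated on).
#' @param model model label to record.
#' @export
readContagionRuns <- function(eventsPath, summariesPath, nodes,
                              model = "reloaded") {
  sm <- utils::read.csv(summariesPath, stringsAsFactors = FALSE)
  sm$seed <- match(sm$seed, nodes)
  if (anyNA(sm$seed)) stop("summary seed ids not all present in `nodes`")
  lines <- readLines(eventsPath)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    recs <- lapply(lines, jsonlite::fromJSON)
    cnt <- vapply(recs, function(r) length(r$attribution), integer(1L))
    ev <- data.frame(
      run = rep.int(vapply(recs, function(r) as.integer(r$run),
                           integer(1L)), cnt),
      time = rep.int(vapply(recs, function(r) as.numeric(r$t),
                            numeric(1L)), cnt),
      infectee = rep.int(match(vapply(recs, function(r) r$infectee,
                                      character(1L)), nodes), cnt),
      infector = match(unlist(lapply(recs, function(r)
        names(r$attribution))), nodes),
      fraction = unlist(lapply(recs, function(r)
        as.numeric(unlist(r$attribution))), use.names = FALSE),
      mechanism = rep.int(vapply(recs, function(r) r$mechanism,
                                 character(1L)), cnt))
    if (anyNA(ev$infectee) || anyNA(ev$infector))
      stop("event node ids not all present in `nodes`")
  } else {
    ev <- data.frame(run = integer(), time = numeric(),
                     infectee = integer(), infector = integer(),
                     fraction = numeric(), mechanism = character())
  }
  new("ContagionRuns", events = ev, summaries = sm,
      stages = data.frame(run = integer(), node = integer(),
                          stage = character(), time = numeric()),
      nodes = nodes, model = model, nRuns = as.integer(nrow(sm)))
}
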