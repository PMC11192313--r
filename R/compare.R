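#' Cosine similarity between two infection patterns
#'
#' Both C matrices are flattened row-major over the shared node index
#' (zeros included, so supports need not match) and the cosine similarity
#' v.w / (|v||w|) of the two vectors is returned; non-negativity of C
#' confines the value to [0, 1].
#'
#' @param p1,p2 \linkS4class{InfectionPattern} objects over the same node
#'   index.
#' @return similarity in [0, 1].
#' @export
cosineSimilarity <- function(p1, p2) {
  stopifnot(is(p1, "InfectionPattern"), is(p2, "InfectionPattern"))
  if (!identical(p1@nodes, p2@nodes))
    stop("patterns must share the same node index")
  n1 <- sqrt(sum(p1@C^2))
  n2 <- sqrt(sum(p2@C^2))
  if (n1 == 0 || n2 == 0)
    stop("cosine similarity undefined for an all-zero pattern")
  as.numeric(sum(p1@C * p2@C) / (n1 * n2))
}

#' Rank agreement of spreader/receiver indices across two conditions
#'
#' Kendall rank correlation (tau-b, midranks for ties) of the chosen node
#' index between two conditions on the same node set.
#'
#' @param idx1,idx2 data.frames as returned by \code{\link{nodeIndices}}.
#' @param which "spreader" or "receiver".
#' @return rank correlation in [-1, 1].
#' @export
rankAgreement <- function(idx1, idx2, which = c("spreader", "receiver")) {
  which <- match.arg(which)
  if (!setequal(idx1$node, idx2$node))
    stop("the two index tables must cover the same node set")
  v1 <- idx1[[which]]
  v2 <- idx2[[which]][match(idx1$node, idx2$node)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("rank correlation undefined for a constant index vector")
  stats::cor(v1, v2, method = "kendall")
}

#' Assemble an experiment configuration
#'
#' @param substrate a \linkS4class{WeightedContactGraph} or
#'   \linkS4class{WeightedHypergraph}.
#' @param conditions list of conditions; each a list with \code{label},
#'   \code{params} (a model parameter object) and optionally
#'   \code{targetR0} (beta is then calibrated before simulating).
#' @param nRuns runs per condition (after conditioning, if a window is set).
#' @param rngSeed integer root seed for the whole experiment.
#' @param window optional closed attack-rate window \code{c(lo, hi)}; runs
#'   are resampled until \code{nRuns} fall inside it.
#' @param maxAttemptFactor attempt ceiling for conditioning, as a multiple
#'   of \code{nRuns} (default 100).
#' @param calibration list of extra arguments passed to
#'   \code{\link{calibrateBeta}} (e.g. \code{betaRange},
#'   \code{runsPerPoint}).
#' @param outDir optional directory where runs, patterns, the similarity
#'   matrix and a manifest are written.
#' @return a classed list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(substrate, conditions, nRuns, rngSeed,
                             window = NULL, maxAttemptFactor = 100,
                             calibration = list(), outDir = NULL) {
  stopifnot(length(conditions) >= 1, nRuns >= 1)
  if (!is.null(window))
    stopifnot(length(window) == 2, window[1] >= 0, window[2] <= 1,
              window[1] < window[2])
  labs <- vapply(conditions, function(cn) cn$label, character(1L))
  if (anyDuplicated(labs)) stop("condition labels must be unique")
  structure(list(substrate = substrate, conditions = conditions,
                 nRuns = nRuns, rngSeed = as.integer(rngSeed),
                 window = window, maxAttemptFactor = maxAttemptFactor,
                 calibration = calibration, outDir = outDir),
            class = "ExperimentConfig")
}

# simulate one condition: calibrate if asked, then (conditionally) sample
.condBeta <- function(params) {
  if ("beta" %in% methods::slotNames(class(params))) params@beta
  else NA_real_  # threshold/simplicial conditions have no single beta
}

.simulateCondition <- function(cfg, cond, condSeed) {
  params <- cond$params
  beta <- NULL
  if (!is.null(cond$targetR0)) {
    graph <- if (is(cfg$substrate, "WeightedHypergraph"))
      cfg$substrate@graph else cfg$substrate
    args <- c(list(graph = graph, params = params,
                   targetR0 = cond$targetR0, rngSeed = condSeed),
              cfg$calibration)
    beta <- do.call(calibrateBeta, args)
    params@beta <- as.numeric(beta)
  }
  if (is.null(cfg$window)) {
    runs <- runSimulations(cfg$substrate, params, cfg$nRuns,
                           rngSeed = condSeed + 1L)
    return(list(runs = runs, params = params, beta = .condBeta(params)))
  }
  quota <- cfg$nRuns
  ceilingN <- cfg$maxAttemptFactor * quota
  kept <- NULL
  attempts <- 0L
  batch <- 0L
  while (is.null(kept) || kept@nRuns < quota) {
    if (attempts >= ceilingN)
      stop(sprintf(
        "conditioning ceiling reached: %d runs in window after %d attempts",
        if (is.null(kept)) 0L else kept@nRuns, attempts))
    batch <- batch + 1L
    nb <- min(quota, ceilingN - attempts)
    runs <- runSimulations(cfg$substrate, params, nb,
                           rngSeed = condSeed + batch)
    attempts <- attempts + nb
    f <- filterRunsByAttackRate(runs, cfg$window[1], cfg$window[2])
    kept <- if (is.null(kept)) f else bindRuns(kept, f)
  }
  kept <- subsetRuns(kept, seq_len(quota))
  list(runs = kept, params = params, beta = .condBeta(params),
       attempts = attempts)
}

#' Pairwise similarity of infection patterns across conditions
#'
#' For each condition: calibrates beta to the target R0 if requested,
#' simulates \code{nRuns} realizations (resampling until the quota of runs
#' falls inside the attack-rate window, if one is set), builds the infection
#' pattern, and fills the symmetric matrix of pairwise cosine similarities.
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @return list with \code{similarity} (symmetric labelled matrix with unit
#'   diagonal), \code{patterns}, \code{runs} and \code{betas}.
#' @export
crossConditionSimilarity <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  nc <- length(cfg$conditions)
  labs <- vapply(cfg$conditions, function(cn) cn$label, character(1L))
  set.seed(cfg$rngSeed)
  condSeeds <- sample.int(.Machine$integer.max %/% 2L, nc)
  sims <- lapply(seq_len(nc), function(k)
    .simulateCondition(cfg, cfg$conditions[[k]], condSeeds[k]))
  patterns <- lapply(sims, function(s) buildInfectionPattern(s$runs))
  names(patterns) <- labs
  S <- diag(1, nc)
  dimnames(S) <- list(labs, labs)
  if (nc > 1)
    for (a in seq_len(nc - 1)) for (b in seq((a + 1), nc))
      S[a, b] <- S[b, a] <- cosineSimilarity(patterns[[a]], patterns[[b]])
  out <- list(similarity = S, patterns = patterns,
              runs = lapply(sims, `[[`, "runs"),
              betas = vapply(sims, `[[`, numeric(1L), "beta"))
  if (!is.null(cfg$outDir)) .persistExperiment(cfg, out)
  out
}

.persistExperiment <- function(cfg, out) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(out$similarity),
                   file.path(cfg$outDir, "similarity.csv"))
  for (lab in names(out$patterns)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lab)
    writePattern(out$patterns[[lab]],
                 file.path(cfg$outDir, paste0("pattern_", safe, ".tsv")))
  }
  for (k in seq_along(out$runs)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_",
                 names(out$patterns)[k])
    writeRunSummaries(out$runs[[k]],
                      file.path(cfg$outDir,
                                paste0("summaries_", safe, ".csv")))
  }
  manifest <- list(
    rngSeed = cfg$rngSeed, nRuns = cfg$nRuns, window = cfg$window,
    labels = names(out$patterns), betas = unname(out$betas),
    package = as.character(utils::packageVersion("contagionPatterns")),
    rVersion = R.version.string)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(NULL)
}

#' Time-matched similarity between a reference and lower-R0 conditions
#'
#' Builds the time-dependent infection pattern C_ref(t) of the reference
#' runs on a time grid and computes, for each test condition, the cosine
#' similarity between C_ref(t) and the test's final pattern. Because the
#' average attack rate of a fast (high-R0) process passes in time through
#' the final attack rates of slower processes, each similarity curve peaks
#' near the time at which the reference's (non-zero) modal attack rate
#' crosses the test's final modal attack rate; both curves are returned so
#' the coincidence can be checked.
#'
#' @param refRuns \linkS4class{ContagionRuns} of the reference condition.
#' @param testRuns list of \linkS4class{ContagionRuns}, one per test
#'   condition (simulated to completion).
#' @param timeGrid sorted ascending evaluation times.
#' @param binWidth,zeroCutoff passed to \code{\link{attackRateMode}}.
#' @param plateauTol tolerance used to locate the similarity maximum:
#'   \code{argmaxTime} is the earliest grid time whose similarity lies
#'   within \code{plateauTol} of the maximum. The default 0 is the strict
#'   argmax; a small positive value (e.g. 0.002) makes the location robust
#'   when the curve rises to a flat plateau whose top is set by Monte Carlo
#'   noise, in which case the earliest attainment is the meaningful one.
#' @return list with \code{time}, \code{similarity} (grid x tests matrix),
#'   \code{refModeCurve}, \code{testFinalModes}, \code{argmaxTime} and
#'   \code{crossTime} (first grid time at which the reference mode curve
#'   reaches each test's final mode).
#' @export
timeMatchedSimilarity <- function(refRuns, testRuns, timeGrid,
                                  binWidth = 0.02, zeroCutoff = 0.1,
                                  plateauTol = 0) {
  if (is.unsorted(timeGrid)) stop("timeGrid must be sorted ascending")
  if (is(testRuns, "ContagionRuns")) testRuns <- list(testRuns)
  refCurve <- timePatternCurve(refRuns, timeGrid)
  testPatterns <- lapply(testRuns, buildInfectionPattern)
  # before the first contagion event C_ref(t) is all-zero and the
  # similarity is undefined; report NA there instead of failing
  cosOrNA <- function(a, b) tryCatch(cosineSimilarity(a, b),
                                     error = function(e) NA_real_)
  S <- vapply(testPatterns, function(tp)
    vapply(refCurve, function(rp) cosOrNA(rp, tp), numeric(1L)),
    numeric(length(timeGrid)))
  S <- matrix(S, nrow = length(timeGrid))
  labs <- names(testRuns)
  if (is.null(labs)) labs <- paste0("test", seq_along(testRuns))
  dimnames(S) <- list(as.character(timeGrid), labs)
  refModeCurve <- vapply(timeGrid, function(tc)
    attackRateMode(attackRateAtTime(refRuns, tc), binWidth, zeroCutoff),
    numeric(1L))
  finalModes <- vapply(testRuns, function(tr)
    attackRateMode(tr, binWidth, zeroCutoff), numeric(1L))
  argmaxTime <- apply(S, 2L, function(s) {
    top <- max(s, na.rm = TRUE)
    timeGrid[which(!is.na(s) & s >= top - plateauTol)[1L]]
  })
  crossTime <- vapply(finalModes, function(m) {
    hit <- which(!is.na(refModeCurve) & refModeCurve >= m)
    if (length(hit)) timeGrid[hit[1L]] else NA_real_
  }, numeric(1L))
  list(time = timeGrid, similarity = S, refModeCurve = refModeCurve,
       testFinalModes = finalModes, argmaxTime = argmaxTime,
       crossTime = crossTime)
}
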