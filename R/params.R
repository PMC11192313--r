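#' @title Model parameter containers
#' @description S4 containers for the transmission models. All rates are per
#'   unit time per unit link weight; since the substrates are static, a
#'   common rescaling of all rates only changes the global time scale, so
#'   parameters of order 1 are used throughout.
#' @name model-params
NULL

#' SimpleParams: SIR / SEIR simple-contagion parameters
#'
#' @slot modelKind one of "SIR", "SEIRe1", "SEIRe4", "SEIRi4", "SEIRe1v025",
#'   "SEIRe4v025", "SEIRi4v025".
#' @slot beta transmission-rate scale: a susceptible node i is infected by an
#'   infectious neighbour j with rate beta * W[ij].
#' @slot muI inverse mean infectious duration.
#' @slot muE inverse mean exposed (latent, non-infectious) duration; NA for
#'   SIR.
#' @slot etaE,etaI ratio of the standard deviation to the mean of the
#'   gamma-distributed stage duration; 1 recovers the exponential
#'   (Markovian) case.
#' @exportClass SimpleParams
setClass("SimpleParams",
  representation(modelKind = "character", beta = "numeric", muI = "numeric",
                 muE = "numeric", etaE = "numeric", etaI = "numeric"))

setValidity("SimpleParams", function(object) {
  if (object@beta < 0) return("beta must be >= 0")
  if (object@muI <= 0) return("muI must be > 0")
  if (!is.na(object@muE) && object@muE <= 0) return("muE must be > 0")
  if (object@etaI <= 0 || object@etaI > 1) return("etaI must be in (0, 1]")
  if (!is.na(object@etaE) && (object@etaE <= 0 || object@etaE > 1))
    return("etaE must be in (0, 1]")
  TRUE
})

#' CovidParams: multi-stage COVID-like model parameters
#'
#' Course of disease: exposed (not contagious) -> pre-symptomatic infectious
#' -> either clinical (with probability pC) or sub-clinical infection. Stage
#' durations are gamma-distributed with the stated mean and standard
#' deviation; the three infectious stages transmit at relative rates rP
#' (pre-symptomatic), rSc (sub-clinical) and 1 (clinical) times beta * W[ij].
#'
#' @slot beta transmission-rate scale.
#' @slot tauE,sigmaE mean and sd of the exposed duration (default 4, 2.3).
#' @slot tauP,sigmaP mean and sd of the pre-symptomatic duration (1.8, 1.8).
#' @slot tauI,sigmaI mean and sd of the infectious duration (5, 2.0).
#' @slot pC probability of the clinical course (0.5).
#' @slot rP,rSc relative transmissibility of the pre-symptomatic and
#'   sub-clinical stages (0.55, 0.55).
#' @exportClass CovidParams
setClass("CovidParams",
  representation(beta = "numeric", tauE = "numeric", sigmaE = "numeric",
                 tauP = "numeric", sigmaP = "numeric", tauI = "numeric",
                 sigmaI = "numeric", pC = "numeric", rP = "numeric",
                 rSc = "numeric"))

setValidity("CovidParams", function(object) {
  if (object@beta < 0) return("beta must be >= 0")
  vals <- c(object@tauE, object@sigmaE, object@tauP, object@sigmaP,
            object@tauI, object@sigmaI)
  if (any(vals <= 0)) return("durations and sds must be positive")
  if (object@pC < 0 || object@pC > 1) return("pC must be in [0, 1]")
  if (object@rP < 0 || object@rP > 1 || object@rSc < 0 || object@rSc > 1)
    return("relative transmissibilities must be in [0, 1]")
  TRUE
})

#' SimplicialParams: simplicial-contagion parameters
#'
#' @slot betaLink pairwise rate scale: infection with rate betaLink * W[ij]
#'   from each infectious neighbour.
#' @slot betaTriad triadic rate scale: infection with rate betaTriad *
#'   W[ijk] from each triad whose other two members are both infectious.
#' @slot muI recovery rate.
#' @exportClass SimplicialParams
setClass("SimplicialParams",
  representation(betaLink = "numeric", betaTriad = "numeric",
                 muI = "numeric"))

setValidity("SimplicialParams", function(object) {
  if (object@betaLink < 0 || object@betaTriad < 0)
    return("rates must be >= 0")
  if (object@muI <= 0) return("muI must be > 0")
  TRUE
})

#' ThresholdParams: weighted threshold-contagion parameters
#'
#' @slot theta threshold in (0, 1): a susceptible node becomes infected when
#'   the weight of its connections to currently infectious nodes, divided by
#'   the total weight of all its connections, strictly exceeds theta.
#' @slot muI recovery rate; per synchronous step an infectious node recovers
#'   with probability 1 - exp(-muI * dt).
#' @slot dt synchronous step length.
#' @exportClass ThresholdParams
setClass("ThresholdParams",
  representation(theta = "numeric", muI = "numeric", dt = "numeric"))

setValidity("ThresholdParams", function(object) {
  if (object@theta <= 0 || object@theta >= 1)
    return("theta must be in (0, 1)")
  if (object@muI <= 0) return("muI must be > 0")
  if (object@dt <= 0) return("dt must be > 0")
  TRUE
})

.simpleModelDefaults <- list(
  SIR        = list(muI = 0.25, muE = NA_real_, etaE = NA_real_, etaI = 1),
  SEIRe1     = list(muI = 1,    muE = 1,    etaE = 1,    etaI = 1),
  SEIRe4     = list(muI = 1,    muE = 0.25, etaE = 1,    etaI = 1),
  SEIRi4     = list(muI = 0.25, muE = 1,    etaE = 1,    etaI = 1),
  SEIRe1v025 = list(muI = 1,    muE = 1,    etaE = 0.25, etaI = 0.25),
  SEIRe4v025 = list(muI = 1,    muE = 0.25, etaE = 0.25, etaI = 0.25),
  SEIRi4v025 = list(muI = 0.25, muE = 1,    etaE = 0.25, etaI = 0.25))

#' Construct simple-contagion model parameters
#'
#' Presets the seven standard variants: plain SIR (muI = 0.25); Markovian
#' SEIR with all rates 1 (SEIRe1), with a four-fold longer exposed stage
#' (SEIRe4) or infectious stage (SEIRi4); and their non-Markovian
#' counterparts (suffix v025) in which the gamma-distributed stage durations
#' keep the same means but have their standard deviations reduced to a
#' quarter of the mean (eta = 0.25). Any preset value can be overridden.
#'
#' @param modelKind model name (see above).
#' @param beta transmission-rate scale.
#' @param muI,muE,etaE,etaI optional overrides of the preset values.
#' @return a \linkS4class{SimpleParams} object.
#' @export
simpleParams <- function(modelKind = c("SIR", "SEIRe1", "SEIRe4", "SEIRi4",
                                       "SEIRe1v025", "SEIRe4v025",
                                       "SEIRi4v025"),
                         beta = 1, muI = NULL, muE = NULL, etaE = NULL,
                         etaI = NULL) {
  modelKind <- match.arg(modelKind)
  d <- .simpleModelDefaults[[modelKind]]
  new("SimpleParams", modelKind = modelKind, beta = beta,
      muI = if (is.null(muI)) d$muI else muI,
      muE = if (is.null(muE)) d$muE else muE,
      etaE = if (is.null(etaE)) d$etaE else etaE,
      etaI = if (is.null(etaI)) d$etaI else etaI)
}

#' Construct COVID-like model parameters
#'
#' Defaults are the standard multi-stage parameterization: exposed 4 +- 2.3,
#' pre-symptomatic 1.8 +- 1.8, infectious 5 +- 2.0 time units, clinical
#' probability 0.5, relative transmissibilities 0.55 (pre-symptomatic and
#' sub-clinical).
#'
#' @param beta transmission-rate scale.
#' @param tauE,sigmaE,tauP,sigmaP,tauI,sigmaI,pC,rP,rSc see
#'   \linkS4class{CovidParams}.
#' @return a \linkS4class{CovidParams} object.
#' @export
covidParams <- function(beta = 1, tauE = 4, sigmaE = 2.3, tauP = 1.8,
                        sigmaP = 1.8, tauI = 5, sigmaI = 2, pC = 0.5,
                        rP = 0.55, rSc = 0.55) {
  new("CovidParams", beta = beta, tauE = tauE, sigmaE = sigmaE, tauP = tauP,
      sigmaP = sigmaP, tauI = tauI, sigmaI = sigmaI, pC = pC, rP = rP,
      rSc = rSc)
}

#' @rdname simulateSimplicial
#' @param betaLink,betaTriad,muI simplicial rates (see
#'   \linkS4class{SimplicialParams}).
#' @export
simplicialParams <- function(betaLink = 1, betaTriad = 1, muI = 1) {
  new("SimplicialParams", betaLink = betaLink, betaTriad = betaTriad,
      muI = muI)
}

#' @rdname simulateThreshold
#' @param theta,muI,dt threshold-model parameters (see
#'   \linkS4class{ThresholdParams}).
#' @export
thresholdParams <- function(theta = 0.3, muI = 1, dt = 1) {
  new("ThresholdParams", theta = theta, muI = muI, dt = dt)
}

# gamma parameterized by (mean, sd): shape = (mean/sd)^2, scale = sd^2/mean;
# sd = mean recovers the exponential distribution
.rgammaMS <- function(n, mean, sd) {
  stats::rgamma(n, shape = (mean / sd)^2, scale = sd^2 / mean)
}

# stage course of one newly infected node: list of parallel vectors
# (stage, duration, r) with r the relative transmissibility in the stage;
# plain lists keep the simulator's inner loop cheap
.drawCourse <- function(params) {
  if (is(params, "SimpleParams")) {
    tauI <- 1 / params@muI
    if (params@modelKind == "SIR") {
      list(stage = "I",
           duration = .rgammaMS(1L, tauI, params@etaI * tauI), r = 1)
    } else {
      tauE <- 1 / params@muE
      list(stage = c("E", "I"),
           duration = c(.rgammaMS(1L, tauE, params@etaE * tauE),
                        .rgammaMS(1L, tauI, params@etaI * tauI)),
           r = c(0, 1))
    }
  } else if (is(params, "CovidParams")) {
    clinical <- stats::runif(1L) < params@pC
    list(stage = c("E", "P", if (clinical) "Ic" else "Isc"),
         duration = c(.rgammaMS(1L, params@tauE, params@sigmaE),
                      .rgammaMS(1L, params@tauP, params@sigmaP),
                      .rgammaMS(1L, params@tauI, params@sigmaI)),
         r = c(0, params@rP, if (clinical) 1 else params@rSc))
  } else {
    stop("unsupported parameter class: ", class(params))
  }
}

#' Sample stage-duration courses of a simple-contagion model
#'
#' Draws \code{n} independent courses of disease (the sequence of stages a
#' newly infected node passes through, with durations and relative
#' transmissibilities), as used inside the event-driven simulator. Useful to
#' verify stage-duration moments and branching probabilities.
#'
#' @param params a \linkS4class{SimpleParams} or \linkS4class{CovidParams}
#'   object.
#' @param n number of courses.
#' @param rngSeed integer seed.
#' @return data.frame with columns \code{sample}, \code{stage},
#'   \code{duration}, \code{r}.
#' @export
sampleStageDurations <- function(params, n, rngSeed) {
  set.seed(as.integer(rngSeed))
  out <- lapply(seq_len(n), function(s)
    cbind(sample = s, as.data.frame(.drawCourse(params))))
  do.call(rbind, out)
}
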