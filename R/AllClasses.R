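#' @import methods
NULL

.checkProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    return(sprintf("'%s' must be a single probability in [0, 1]", name))
  NULL
}

.checkCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != as.integer(x))
    return(sprintf("'%s' must be a single integer >= 1", name))
  NULL
}

#' Parameters of the latent occupancy dynamics
#'
#' Bundles the three state parameters of a multi-season occupancy process:
#' initial occupancy probability \code{psi}, per-transition colonization
#' probability \code{gamma}, and per-transition extinction probability
#' \code{epsilon}.
#'
#' @slot psi Probability a site is occupied in the first season.
#' @slot gamma Probability an unoccupied site becomes occupied at the next
#'   season transition.
#' @slot epsilon Probability an occupied site becomes unoccupied at the next
#'   season transition.
#'
#' @param psi,gamma,epsilon Probabilities in \[0, 1\].
#' @return A \code{DynamicsParams} object.
#' @examples
#' DynamicsParams(psi = 0.6, gamma = 0.25, epsilon = 0.25)
#' @export DynamicsParams
#' @exportClass DynamicsParams
DynamicsParams <- setClass("DynamicsParams",
  representation(psi = "numeric", gamma = "numeric", epsilon = "numeric"),
  validity = function(object) {
    msgs <- c(.checkProb(object@psi, "psi"),
              .checkProb(object@gamma, "gamma"),
              .checkProb(object@epsilon, "epsilon"))
    if (length(msgs)) msgs else TRUE
  })

#' @rdname DynamicsParams-class
#' @usage NULL
setMethod("initialize", "DynamicsParams",
  function(.Object, psi = 0.6, gamma = 0.25, epsilon = 0.25, ...) {
    callNextMethod(.Object, psi = psi, gamma = gamma, epsilon = epsilon, ...)
  })

#' Audio recording schedule
#'
#' Describes when the autonomous recording units sample audio: a fixed number
#' of recorded minutes per day, for a fixed number of days in each season.
#' The recorded minutes are treated as one contiguous block; nothing
#' downstream depends on their clock-time position within the day.
#'
#' @slot daysPerSeason Number of monitored days per season.
#' @slot minutesPerDay Number of recorded minutes per day.
#' @slot nSeasons Number of seasons.
#'
#' @param daysPerSeason,minutesPerDay,nSeasons Positive integers. Defaults
#'   describe two 30-day seasons sampled 5 minutes per day.
#' @return A \code{RecordingSchedule} object.
#' @examples
#' RecordingSchedule()                      # 30 d x 5 min x 2 seasons
#' RecordingSchedule(daysPerSeason = 10)
#' @export RecordingSchedule
#' @exportClass RecordingSchedule
RecordingSchedule <- setClass("RecordingSchedule",
  representation(daysPerSeason = "integer", minutesPerDay = "integer",
                 nSeasons = "integer"),
  validity = function(object) {
    msgs <- c(.checkCount(object@daysPerSeason, "daysPerSeason"),
              .checkCount(object@minutesPerDay, "minutesPerDay"),
              .checkCount(object@nSeasons, "nSeasons"))
    if (length(msgs)) msgs else TRUE
  })

#' @rdname RecordingSchedule-class
#' @usage NULL
setMethod("initialize", "RecordingSchedule",
  function(.Object, daysPerSeason = 30L, minutesPerDay = 5L,
           nSeasons = 2L, ...) {
    callNextMethod(.Object,
                   daysPerSeason = as.integer(daysPerSeason),
                   minutesPerDay = as.integer(minutesPerDay),
                   nSeasons = as.integer(nSeasons), ...)
  })

#' Classifier score distributions
#'
#' An automated detection classifier is characterised by the beta
#' distributions from which it draws the target signal probability (score)
#' it assigns to each event-level detection: one beta for true target
#' signals, one for false alarms.
#'
#' `goodClassifier()` assigns high scores to targets and low scores to false
#' alarms (Beta(4, 1) and Beta(1, 4); means 0.8 and 0.2).
#' `badClassifier()` cannot tell them apart (Beta(3, 3) for both; mean 0.5).
#'
#' @slot targetAlpha,targetBeta Beta shape parameters for true target
#'   signals.
#' @slot faAlpha,faBeta Beta shape parameters for false alarms.
#' @slot label Human-readable label.
#'
#' @param targetAlpha,targetBeta,faAlpha,faBeta Positive beta shape
#'   parameters.
#' @param label Character label for reporting.
#' @return A \code{ClassifierSpec} object.
#' @examples
#' goodClassifier()
#' badClassifier()
#' ClassifierSpec(2, 1, 1, 2, label = "custom")
#' @export ClassifierSpec
#' @exportClass ClassifierSpec
ClassifierSpec <- setClass("ClassifierSpec",
  representation(targetAlpha = "numeric", targetBeta = "numeric",
                 faAlpha = "numeric", faBeta = "numeric", label = "character"),
  validity = function(object) {
    shp <- c(object@targetAlpha, object@targetBeta,
             object@faAlpha, object@faBeta)
    if (any(!is.finite(shp)) || any(shp <= 0))
      return("all beta shape parameters must be finite and > 0")
    TRUE
  })

#' @rdname ClassifierSpec-class
#' @usage NULL
setMethod("initialize", "ClassifierSpec",
  function(.Object, targetAlpha = 4, targetBeta = 1, faAlpha = 1,
           faBeta = 4, label = "good", ...) {
    callNextMethod(.Object, targetAlpha = targetAlpha,
                   targetBeta = targetBeta, faAlpha = faAlpha,
                   faBeta = faBeta, label = label, ...)
  })

#' @rdname ClassifierSpec-class
#' @export
goodClassifier <- function() {
  ClassifierSpec(targetAlpha = 4, targetBeta = 1, faAlpha = 1, faBeta = 4,
                 label = "good")
}

#' @rdname ClassifierSpec-class
#' @export
badClassifier <- function() {
  ClassifierSpec(targetAlpha = 3, targetBeta = 3, faAlpha = 3, faBeta = 3,
                 label = "bad")
}

#' Encounter-history aggregation settings
#'
#' Controls how event-level detections are collapsed into survey-level
#' encounter-history codes: the number of consecutive days pooled into one
#' survey, the detection threshold applied to the aggregated probability
#' that a survey contains at least one true target signal, and the
#' proportion of site-surveys designated for a posteriori manual
#' confirmation.
#'
#' @slot aggregationDays Days pooled into one survey (must divide the season
#'   length).
#' @slot threshold Survey-level detection threshold in (0, 1\]; an
#'   unconfirmed survey is coded 1 when its aggregated detection probability
#'   meets or exceeds it.
#' @slot confirmProp Proportion of all site-surveys manually confirmed.
#'
#' @param aggregationDays Positive integer (1 or 3 in the simulation study).
#' @param threshold Probability in (0, 1\].
#' @param confirmProp Probability in \[0, 1\].
#' @return An \code{AggregationConfig} object.
#' @examples
#' AggregationConfig(aggregationDays = 1, threshold = 0.95,
#'                   confirmProp = 0.05)
#' @export AggregationConfig
#' @exportClass AggregationConfig
AggregationConfig <- setClass("AggregationConfig",
  representation(aggregationDays = "integer", threshold = "numeric",
                 confirmProp = "numeric"),
  validity = function(object) {
    msgs <- c(.checkCount(object@aggregationDays, "aggregationDays"),
              .checkProb(object@threshold, "threshold"),
              .checkProb(object@confirmProp, "confirmProp"))
    if (is.null(msgs) && object@threshold == 0)
      msgs <- "'threshold' must be in (0, 1]"
    if (length(msgs)) msgs else TRUE
  })

#' @rdname AggregationConfig-class
#' @usage NULL
setMethod("initialize", "AggregationConfig",
  function(.Object, aggregationDays = 1L, threshold = 0.95,
           confirmProp = 0.05, ...) {
    callNextMethod(.Object, aggregationDays = as.integer(aggregationDays),
                   threshold = threshold, confirmProp = confirmProp, ...)
  })

#' Latent occupancy states
#'
#' A binary site-by-season matrix of the latent occupancy process;
#' \code{z[i, s] == 1} means site \code{i} is occupied in season \code{s}.
#' Usually created by [simulateOccupancy()].
#'
#' @slot z Integer matrix (sites x seasons) with entries in \{0, 1\}.
#'
#' @param z Binary matrix, sites in rows and seasons in columns.
#' @return An \code{OccupancyState} object.
#' @seealso [simulateOccupancy()], [occupancyMatrix()]
#' @export OccupancyState
#' @exportClass OccupancyState
OccupancyState <- setClass("OccupancyState",
  representation(z = "matrix"),
  validity = function(object) {
    z <- object@z
    if (!is.numeric(z) || anyNA(z) || !all(z %in% c(0, 1)))
      return("'z' must be a binary (0/1) matrix")
    if (nrow(z) < 1L || ncol(z) < 1L)
      return("'z' must have at least one site and one season")
    TRUE
  })

#' Event-level detections
#'
#' The stream of event-level detections produced by the automated detection
#' system: each row is one flagged event, located at (site, season, day,
#' minute), carrying its latent truth (\code{is_target}: 1 = true target
#' signal, 0 = false alarm) and the classifier-assigned target signal
#' probability \code{score}. Scores are \code{NA} until assigned by
#' [assignTargetProbabilities()].
#'
#' @slot events A \code{data.frame} with columns \code{site_id},
#'   \code{season}, \code{day}, \code{minute}, \code{is_target},
#'   \code{score}.
#'
#' @param events Data frame with the columns above.
#' @return An \code{EventTable} object.
#' @seealso [simulateCallEvents()], [simulateFalseAlarmEvents()],
#'   [assignTargetProbabilities()]
#' @export EventTable
#' @exportClass EventTable
EventTable <- setClass("EventTable",
  representation(events = "data.frame"),
  validity = function(object) {
    ev <- object@events
    need <- c("site_id", "season", "day", "minute", "is_target", "score")
    if (!all(need %in% names(ev)))
      return(paste("'events' must have columns",
                   paste(need, collapse = ", ")))
    if (nrow(ev)) {
      if (!all(ev$is_target %in% c(0, 1)))
        return("'is_target' must be 0 or 1")
      sc <- ev$score[!is.na(ev$score)]
      if (length(sc) && (any(sc <= 0) || any(sc >= 1)))
        return("assigned scores must lie strictly in (0, 1)")
      if (any(ev$day < 1) || any(ev$minute < 1))
        return("'day' and 'minute' must be >= 1")
    }
    TRUE
  })

#' @rdname EventTable-class
#' @usage NULL
setMethod("initialize", "EventTable",
  function(.Object, events = .emptyEvents(), ...) {
    callNextMethod(.Object, events = events, ...)
  })

.emptyEvents <- function() {
  data.frame(site_id = integer(), season = integer(), day = integer(),
             minute = integer(), is_target = integer(), score = numeric())
}

#' Three-state encounter histories
#'
#' A site-by-survey matrix of encounter-history codes: 0 (no survey-level
#' detection), 1 (uncertain detection via the automated system only), or
#' 2 (certain detection: the survey was manually confirmed and contained at
#' least one verified target signal). Per-survey metadata records which
#' season and day range each survey covers, and a parallel binary matrix
#' records which site-surveys were designated for manual confirmation.
#'
#' @slot codes Integer matrix (sites x surveys) with values in \{0, 1, 2\}.
#' @slot surveyMeta \code{data.frame} with columns \code{survey},
#'   \code{season}, \code{first_day}, \code{last_day} (days within season).
#' @slot confirmed Binary matrix (sites x surveys); 1 marks a manually
#'   confirmed site-survey.
#'
#' @param codes,surveyMeta,confirmed See slots.
#' @return An \code{EncounterHistory} object.
#' @seealso [buildEncounterHistory()], [encounterCodes()], [surveyMeta()]
#' @export EncounterHistory
#' @exportClass EncounterHistory
EncounterHistory <- setClass("EncounterHistory",
  representation(codes = "matrix", surveyMeta = "data.frame",
                 confirmed = "matrix"),
  validity = function(object) {
    if (!all(object@codes %in% c(0, 1, 2)))
      return("'codes' must contain only 0, 1 or 2")
    if (!all(dim(object@confirmed) == dim(object@codes)))
      return("'confirmed' must have the same dimensions as 'codes'")
    if (!all(object@confirmed %in% c(0, 1)))
      return("'confirmed' must be binary")
    if (any(object@codes == 2 & object@confirmed == 0))
      return("code 2 may occur only at confirmed site-surveys")
    need <- c("survey", "season", "first_day", "last_day")
    if (!all(need %in% names(object@surveyMeta)))
      return(paste("'surveyMeta' must have columns",
                   paste(need, collapse = ", ")))
    if (nrow(object@surveyMeta) != ncol(object@codes))
      return("'surveyMeta' must have one row per survey")
    s <- object@surveyMeta$season
    if (is.unsorted(s))
      return("surveys must be ordered by season")
    TRUE
  })

#' Parameters of the multiple-detection-states occupancy model
#'
#' The six parameters of the dynamic occupancy model with uncertain (1) and
#' certain (2) detection states: the state parameters \code{psi} (initial
#' occupancy), \code{gamma} (colonization) and \code{epsilon} (extinction),
#' and the detection parameters \code{p10} (probability of an uncertain
#' detection at an unoccupied site: survey-level false positive),
#' \code{p11} (probability of a detection of either state at an occupied
#' site: survey-level true positive) and \code{b} (probability that a
#' detection at an occupied site is certain, i.e. manually verified).
#'
#' The observation model factorises as P(2 | occupied) = p11 * b,
#' P(1 | occupied) = p11 * (1 - b), P(1 | unoccupied) = p10, and certain
#' detections are impossible at unoccupied sites.
#'
#' @slot psi,gamma,epsilon State parameters (see [DynamicsParams()]).
#' @slot p10,p11,b Detection parameters, all probabilities.
#'
#' @param psi,gamma,epsilon,p10,p11,b Probabilities in \[0, 1\].
#' @return A \code{MillerParams} object.
#' @examples
#' MillerParams(psi = 0.6, gamma = 0.25, epsilon = 0.25,
#'              p10 = 0.1, p11 = 0.6, b = 0.1)
#' @export MillerParams
#' @exportClass MillerParams
MillerParams <- setClass("MillerParams",
  representation(psi = "numeric", gamma = "numeric", epsilon = "numeric",
                 p10 = "numeric", p11 = "numeric", b = "numeric"),
  validity = function(object) {
    msgs <- c(.checkProb(object@psi, "psi"),
              .checkProb(object@gamma, "gamma"),
              .checkProb(object@epsilon, "epsilon"),
              .checkProb(object@p10, "p10"),
              .checkProb(object@p11, "p11"),
              .checkProb(object@b, "b"))
    if (length(msgs)) msgs else TRUE
  })

#' @rdname MillerParams-class
#' @usage NULL
setMethod("initialize", "MillerParams",
  function(.Object, psi = 0.5, gamma = 0.1, epsilon = 0.1, p10 = 0.05,
           p11 = 0.5, b = 0.1, ...) {
    callNextMethod(.Object, psi = psi, gamma = gamma, epsilon = epsilon,
                   p10 = p10, p11 = p11, b = b, ...)
  })

#' Result of a maximum-likelihood model fit
#'
#' Holds the parameter estimates, the minimised negative log-likelihood,
#' convergence diagnostics and boundary flags from [fitMillerModel()].
#'
#' @slot estimates A [MillerParams-class] object with the estimates.
#' @slot negLogLik Minimised negative log-likelihood.
#' @slot converged \code{TRUE} when the optimizer reported success, the
#'   negative log-likelihood is finite, and the gradient norm is below
#'   tolerance.
#' @slot nIterations Number of objective evaluations used.
#' @slot gradNorm Max-norm of the numerical gradient (logit scale) at the
#'   optimum.
#' @slot boundaryFlags Named logical vector; \code{TRUE} where an estimate
#'   lies within tolerance of 0 or 1.
#'
#' @seealso [fitMillerModel()], [estimates()], [converged()]
#' @exportClass MillerFit
setClass("MillerFit",
  representation(estimates = "MillerParams", negLogLik = "numeric",
                 converged = "logical", nIterations = "integer",
                 gradNorm = "numeric", boundaryFlags = "logical"))

#' Survey-level true and false positive rates
#'
#' Summarises an encounter history against the latent truth: \code{tpRate}
#' is the proportion of occupied site-surveys with a detection (code 1
#' or 2); \code{fpRate} is the proportion of unoccupied site-surveys with a
#' (necessarily mistaken) detection. Either rate is \code{NA} when its
#' denominator is empty.
#'
#' @slot tpRate,fpRate Proportions in \[0, 1\], or \code{NA}.
#' @slot nOccupied,nUnoccupied Denominators (site-survey counts).
#'
#' @seealso [computeSurveyRates()]
#' @exportClass RateSummary
setClass("RateSummary",
  representation(tpRate = "numeric", fpRate = "numeric",
                 nOccupied = "integer", nUnoccupied = "integer"))

#' One simulation scenario
#'
#' Bundles every knob of one simulation scenario: the latent dynamics, the
#' call production and false alarm rates (per hour), the classifier, the
#' recording schedule, the aggregation settings, the number of sites and
#' the scenario seed.
#'
#' @slot dynamics A [DynamicsParams-class].
#' @slot lambdaC Species call production rate at occupied sites, calls/hour.
#' @slot lambdaF Soundscape false alarm rate, false alarms/hour.
#' @slot classifier A [ClassifierSpec-class].
#' @slot schedule A [RecordingSchedule-class].
#' @slot agg An [AggregationConfig-class].
#' @slot nSites Number of monitored sites.
#' @slot seed Scenario-level random seed.
#' @slot label Scenario label used in result tables.
#'
#' @param dynamics,lambdaC,lambdaF,classifier,schedule,agg,nSites,seed,label
#'   See slots. Defaults give the high-occupancy/high-turnover dynamics,
#'   low call rate, good classifier, 100 sites, two 30-day seasons and
#'   1-day aggregation at threshold 0.95 with 5\% confirmation.
#' @return A \code{ScenarioConfig} object.
#' @seealso [scenarioGrid()], [runReplicate()]
#' @export ScenarioConfig
#' @exportClass ScenarioConfig
ScenarioConfig <- setClass("ScenarioConfig",
  representation(dynamics = "DynamicsParams", lambdaC = "numeric",
                 lambdaF = "numeric", classifier = "ClassifierSpec",
                 schedule = "RecordingSchedule", agg = "AggregationConfig",
                 nSites = "integer", seed = "integer", label = "character"),
  validity = function(object) {
    if (object@lambdaC < 0 || object@lambdaF < 0)
      return("'lambdaC' and 'lambdaF' must be >= 0")
    .checkCount(object@nSites, "nSites") %||% TRUE
  })

#' @rdname ScenarioConfig-class
#' @usage NULL
setMethod("initialize", "ScenarioConfig",
  function(.Object, dynamics = DynamicsParams(), lambdaC = 20,
           lambdaF = 48, classifier = goodClassifier(),
           schedule = RecordingSchedule(), agg = AggregationConfig(),
           nSites = 100L, seed = 1L, label = "", ...) {
    callNextMethod(.Object, dynamics = dynamics, lambdaC = lambdaC,
                   lambdaF = lambdaF, classifier = classifier,
                   schedule = schedule, agg = agg,
                   nSites = as.integer(nSites), seed = as.integer(seed),
                   label = label, ...)
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
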