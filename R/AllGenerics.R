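#' Accessors for acousticOccu objects
#'
#' Small accessor generics: \code{occupancyMatrix} returns the binary
#' site-by-season matrix of an [OccupancyState-class]; \code{eventData}
#' the event \code{data.frame} of an [EventTable-class];
#' \code{encounterCodes}, \code{surveyMeta} and \code{confirmedMask} the
#' components of an [EncounterHistory-class]; \code{estimates},
#' \code{negLogLik}, \code{converged} and \code{boundaryFlags} the
#' components of a [MillerFit-class]; \code{tpRate} and \code{fpRate} the
#' components of a [RateSummary-class]. \code{nSites}/\code{nSeasons}/
#' \code{nSurveys} return dimensions.
#'
#' @param x An object of the documented class.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("occupancyMatrix", function(x) standardGeneric("occupancyMatrix"))

#' @rdname accessors
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' @rdname accessors
#' @export
setGeneric("encounterCodes", function(x) standardGeneric("encounterCodes"))

#' @rdname accessors
#' @export
setGeneric("surveyMeta", function(x) standardGeneric("surveyMeta"))

#' @rdname accessors
#' @export
setGeneric("confirmedMask", function(x) standardGeneric("confirmedMask"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("negLogLik", function(x) standardGeneric("negLogLik"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("boundaryFlags", function(x) standardGeneric("boundaryFlags"))

#' @rdname accessors
#' @export
setGeneric("tpRate", function(x) standardGeneric("tpRate"))

#' @rdname accessors
#' @export
setGeneric("fpRate", function(x) standardGeneric("fpRate"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("nSeasons", function(x) standardGeneric("nSeasons"))

#' @rdname accessors
#' @export
setGeneric("nSurveys", function(x) standardGeneric("nSurveys"))

#' @rdname accessors
setMethod("occupancyMatrix", "OccupancyState", function(x) x@z)

#' @rdname accessors
setMethod("eventData", "EventTable", function(x) x@events)

#' @rdname accessors
setMethod("encounterCodes", "EncounterHistory", function(x) x@codes)

#' @rdname accessors
setMethod("surveyMeta", "EncounterHistory", function(x) x@surveyMeta)

#' @rdname accessors
setMethod("confirmedMask", "EncounterHistory", function(x) x@confirmed)

#' @rdname accessors
setMethod("estimates", "MillerFit", function(x) x@estimates)

#' @rdname accessors
setMethod("negLogLik", "MillerFit", function(x) x@negLogLik)

#' @rdname accessors
setMethod("converged", "MillerFit", function(x) x@converged)

#' @rdname accessors
setMethod("boundaryFlags", "MillerFit", function(x) x@boundaryFlags)

#' @rdname accessors
setMethod("tpRate", "RateSummary", function(x) x@tpRate)

#' @rdname accessors
setMethod("fpRate", "RateSummary", function(x) x@fpRate)

#' @rdname accessors
setMethod("nSites", "OccupancyState", function(x) nrow(x@z))

#' @rdname accessors
setMethod("nSeasons", "OccupancyState", function(x) ncol(x@z))

#' @rdname accessors
setMethod("nSites", "EncounterHistory", function(x) nrow(x@codes))

#' @rdname accessors
setMethod("nSurveys", "EncounterHistory", function(x) ncol(x@codes))

#' Numeric vector of model parameters
#'
#' Converts a [MillerParams-class] or [DynamicsParams-class] bundle to a
#' named numeric vector (order \code{psi, gamma, epsilon, p10, p11, b} or
#' \code{psi, gamma, epsilon}).
#'
#' @param x The parameter object.
#' @param ... Unused.
#' @return A named numeric vector.
#' @export
setMethod("as.numeric", "MillerParams", function(x, ...) {
  c(psi = x@psi, gamma = x@gamma, epsilon = x@epsilon,
    p10 = x@p10, p11 = x@p11, b = x@b)
})

#' @rdname as.numeric-MillerParams-method
#' @export
setMethod("as.numeric", "DynamicsParams", function(x, ...) {
  c(psi = x@psi, gamma = x@gamma, epsilon = x@epsilon)
})

setMethod("show", "DynamicsParams", function(object) {
  cat(sprintf("DynamicsParams: psi = %.3g, gamma = %.3g, epsilon = %.3g\n",
              object@psi, object@gamma, object@epsilon))
})

setMethod("show", "MillerParams", function(object) {
  v <- as.numeric(object)
  cat("MillerParams\n")
  print(round(v, 4))
})

setMethod("show", "OccupancyState", function(object) {
  z <- object@z
  cat(sprintf("OccupancyState: %d sites x %d seasons\n", nrow(z), ncol(z)))
  cat("  occupied fraction per season:",
      paste(sprintf("%.3f", colMeans(z)), collapse = ", "), "\n")
})

setMethod("show", "EventTable", function(object) {
  ev <- object@events
  cat(sprintf("EventTable: %d events (%d target, %d false alarm)\n",
              nrow(ev), sum(ev$is_target == 1), sum(ev$is_target == 0)))
  if (nrow(ev) && !anyNA(ev$score))
    cat(sprintf("  mean score: targets %.3f, false alarms %.3f\n",
                mean(ev$score[ev$is_target == 1]),
                mean(ev$score[ev$is_target == 0])))
  else if (nrow(ev))
    cat("  scores not yet assigned\n")
})

setMethod("show", "EncounterHistory", function(object) {
  cd <- object@codes
  cat(sprintf("EncounterHistory: %d sites x %d surveys\n",
              nrow(cd), ncol(cd)))
  tab <- table(factor(cd, levels = 0:2))
  cat(sprintf("  codes: 0 x %d, 1 x %d, 2 x %d; %d site-surveys confirmed\n",
              tab[["0"]], tab[["1"]], tab[["2"]], sum(object@confirmed)))
})

setMethod("show", "MillerFit", function(object) {
  cat("Multiple-detection-states occupancy model fit\n")
  v <- as.numeric(object@estimates)
  print(round(v, 4))
  cat(sprintf("  negLogLik = %.4f; converged = %s; evaluations = %d\n",
              object@negLogLik, object@converged, object@nIterations))
  if (any(object@boundaryFlags))
    cat("  boundary estimates:",
        paste(names(object@boundaryFlags)[object@boundaryFlags],
              collapse = ", "), "\n")
})

setMethod("show", "RateSummary", function(object) {
  cat(sprintf(
    "RateSummary: tpRate = %.4f (n = %d), fpRate = %.4f (n = %d)\n",
    object@tpRate, object@nOccupied, object@fpRate, object@nUnoccupied))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s'\n", object@label))
  cat(sprintf(
    "  psi = %.2f, gamma = %.2f, epsilon = %.2f; lambdaC = %g/h, lambdaF = %g/h\n",
    object@dynamics@psi, object@dynamics@gamma, object@dynamics@epsilon,
    object@lambdaC, object@lambdaF))
  cat(sprintf(
    "  classifier '%s'; %d sites; %d-d aggregation, threshold %.2f, %.1f%% confirmed\n",
    object@classifier@label, object@nSites, object@agg@aggregationDays,
    object@agg@threshold, 100 * object@agg@confirmProp))
})
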