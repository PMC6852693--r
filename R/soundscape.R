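# Event generation: per recorded minute, event counts are Poisson with the
# hourly rate divided by 60. Counts are drawn for every (site, season, day,
# minute) cell of the schedule at once, then expanded into event rows.
.poissonEvents <- function(cells, ratePerMinute, isTarget) {
  n <- stats::rpois(nrow(cells), ratePerMinute)
  keep <- n > 0L
  if (!any(keep)) return(.emptyEvents())
  idx <- rep(which(keep), n[keep])
  out <- cells[idx, , drop = FALSE]
  out$is_target <- isTarget
  out$score <- NA_real_
  rownames(out) <- NULL
  out
}

.scheduleCells <- function(siteSeasons, schedule) {
  # siteSeasons: data.frame(site_id, season); expand over days and minutes
  d <- schedule@daysPerSeason
  m <- schedule@minutesPerDay
  nc <- nrow(siteSeasons)
  data.frame(
    site_id = rep(siteSeasons$site_id, each = d * m),
    season = rep(siteSeasons$season, each = d * m),
    day = rep(rep(seq_len(d), each = m), times = nc),
    minute = rep(seq_len(m), times = nc * d))
}

#' Simulate species call events at occupied sites
#'
#' Target-species calls are produced only where the species is present.
#' For each recorded minute at an occupied site-season, the number of calls
#' captured by the automated system is Poisson with mean
#' \code{lambdaC / 60}; unoccupied site-seasons produce none.
#'
#' @param occ An [OccupancyState-class] object.
#' @param schedule A [RecordingSchedule-class]; its season count must match
#'   \code{occ}.
#' @param lambdaC Call production rate in calls per hour (>= 0).
#' @return An [EventTable-class] with \code{is_target = 1} rows and
#'   unassigned scores.
#' @examples
#' set.seed(1)
#' occ <- simulateOccupancy(DynamicsParams(0.6, 0.25, 0.25), 10)
#' ev <- simulateCallEvents(occ, RecordingSchedule(), lambdaC = 20)
#' @export
simulateCallEvents <- function(occ, schedule, lambdaC) {
  stopifnot(is(occ, "OccupancyState"), is(schedule, "RecordingSchedule"))
  if (!is.numeric(lambdaC) || length(lambdaC) != 1L || is.na(lambdaC) ||
      lambdaC < 0)
    stop("'lambdaC' must be a single rate >= 0")
  if (ncol(occ@z) != schedule@nSeasons)
    stop("schedule season count does not match the occupancy state")
  occIdx <- which(occ@z == 1L, arr.ind = TRUE)
  if (nrow(occIdx) == 0L || lambdaC == 0)
    return(EventTable(events = .emptyEvents()))
  cells <- .scheduleCells(
    data.frame(site_id = occIdx[, 1L], season = occIdx[, 2L]), schedule)
  EventTable(events = .poissonEvents(cells, lambdaC / 60, 1L))
}

#' Simulate soundscape false alarm events
#'
#' False alarm sources are present in the soundscape at every site
#' regardless of occupancy: for each recorded minute at each site-season the
#' number of events that fool the automated detector is Poisson with mean
#' \code{lambdaF / 60}.
#'
#' @param occ An [OccupancyState-class] object (only its dimensions are
#'   used), or a site count.
#' @param schedule A [RecordingSchedule-class].
#' @param lambdaF False alarm rate in events per hour (>= 0); default 48.
#' @return An [EventTable-class] with \code{is_target = 0} rows and
#'   unassigned scores.
#' @export
simulateFalseAlarmEvents <- function(occ, schedule, lambdaF = 48) {
  stopifnot(is(schedule, "RecordingSchedule"))
  if (!is.numeric(lambdaF) || length(lambdaF) != 1L || is.na(lambdaF) ||
      lambdaF < 0)
    stop("'lambdaF' must be a single rate >= 0")
  ns <- if (is(occ, "OccupancyState")) nrow(occ@z) else as.integer(occ)
  if (ns < 1L) stop("need at least one site")
  if (lambdaF == 0)
    return(EventTable(events = .emptyEvents()))
  siteSeasons <- data.frame(
    site_id = rep(seq_len(ns), times = schedule@nSeasons),
    season = rep(seq_len(schedule@nSeasons), each = ns))
  cells <- .scheduleCells(siteSeasons, schedule)
  EventTable(events = .poissonEvents(cells, lambdaF / 60, 0L))
}

#' Assign classifier scores to event-level detections
#'
#' Draws the target signal probability (score) for every event from the
#' classifier's beta distributions: true target signals from
#' Beta(\code{targetAlpha}, \code{targetBeta}), false alarms from
#' Beta(\code{faAlpha}, \code{faBeta}).
#'
#' @param events An [EventTable-class] with latent \code{is_target} labels.
#' @param spec A [ClassifierSpec-class].
#' @return The [EventTable-class] with scores filled in.
#' @examples
#' set.seed(1)
#' occ <- simulateOccupancy(DynamicsParams(0.6, 0.25, 0.25), 10)
#' ev <- simulateFalseAlarmEvents(occ, RecordingSchedule(), 48)
#' ev <- assignTargetProbabilities(ev, goodClassifier())
#' @export
assignTargetProbabilities <- function(events, spec) {
  stopifnot(is(events, "EventTable"), is(spec, "ClassifierSpec"))
  validObject(spec)
  ev <- events@events
  if (anyNA(ev$is_target))
    stop("every event must carry a latent is_target label")
  tgt <- ev$is_target == 1L
  sc <- numeric(nrow(ev))
  sc[tgt] <- stats::rbeta(sum(tgt), spec@targetAlpha, spec@targetBeta)
  sc[!tgt] <- stats::rbeta(sum(!tgt), spec@faAlpha, spec@faBeta)
  # beta draws can hit 0 or 1 only by floating-point rounding; nudge inside
  eps <- .Machine$double.eps
  ev$score <- pmin(pmax(sc, eps), 1 - eps)
  EventTable(events = ev)
}

#' Simulate a full soundscape for one occupancy realisation
#'
#' Convenience wrapper: species call events at occupied sites, false alarm
#' events everywhere, and classifier scores for all of them, in one call.
#'
#' @inheritParams simulateCallEvents
#' @inheritParams simulateFalseAlarmEvents
#' @param classifier A [ClassifierSpec-class].
#' @return An [EventTable-class] with scores assigned.
#' @export
simulateSoundscape <- function(occ, schedule, lambdaC, lambdaF = 48,
                               classifier = goodClassifier()) {
  calls <- simulateCallEvents(occ, schedule, lambdaC)
  fas <- simulateFalseAlarmEvents(occ, schedule, lambdaF)
  ev <- EventTable(events = rbind(calls@events, fas@events))
  assignTargetProbabilities(ev, classifier)
}
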