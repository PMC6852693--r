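#' Aggregated survey-level detection probability
#'
#' Collapses the classifier scores of all event-level detections within one
#' survey into the probability that at least one of them is a true target
#' signal, using the capture-recapture style complement product:
#' \code{q = 1 - prod(1 - score)}. A survey with no events has \code{q = 0}.
#'
#' @param scores Numeric vector of event scores in \[0, 1\] (possibly
#'   empty).
#' @return The aggregated detection probability \code{q}.
#' @examples
#' surveyDetectionProbability(c(0.15, 0.04, 0.11))  # 0.2736
#' surveyDetectionProbability(c(0.56, 0.88, 0.71))  # ~0.985
#' surveyDetectionProbability(numeric(0))           # 0
#' @export
surveyDetectionProbability <- function(scores) {
  if (length(scores) == 0L) return(0)
  if (!is.numeric(scores) || anyNA(scores) ||
      any(scores < 0) || any(scores > 1))
    stop("'scores' must be probabilities in [0, 1]")
  -expm1(sum(log1p(-scores)))
}

#' Randomly designate site-surveys for manual confirmation
#'
#' Selects \code{floor(confirmProp * nSites * nSurveys)} site-survey units
#' uniformly at random without replacement, pooled over all sites and
#' surveys. Flooring guarantees the stated manual-verification budget is
#' never exceeded.
#'
#' @param nSites,nSurveys Dimensions of the encounter history.
#' @param confirmProp Proportion of site-surveys to confirm, in \[0, 1\].
#' @return A binary \code{nSites} x \code{nSurveys} matrix; 1 = confirmed.
#' @examples
#' set.seed(1)
#' sum(assignConfirmedSurveys(100, 60, 0.05))  # 300
#' @export
assignConfirmedSurveys <- function(nSites, nSurveys, confirmProp) {
  if (!is.numeric(confirmProp) || length(confirmProp) != 1L ||
      is.na(confirmProp) || confirmProp < 0 || confirmProp > 1)
    stop("'confirmProp' must be a probability in [0, 1]")
  nSites <- as.integer(nSites)
  nSurveys <- as.integer(nSurveys)
  total <- nSites * nSurveys
  k <- floor(confirmProp * total)
  conf <- matrix(0L, nSites, nSurveys)
  if (k > 0L) conf[sample.int(total, k)] <- 1L
  conf
}

.surveyLayout <- function(schedule, aggregationDays) {
  d <- schedule@daysPerSeason
  if (d %% aggregationDays != 0L)
    stop(sprintf(
      "aggregationDays (%d) must divide daysPerSeason (%d)",
      aggregationDays, d))
  perSeason <- d %/% aggregationDays
  nSurveys <- perSeason * schedule@nSeasons
  data.frame(
    survey = seq_len(nSurveys),
    season = rep(seq_len(schedule@nSeasons), each = perSeason),
    first_day = rep((seq_len(perSeason) - 1L) * aggregationDays + 1L,
                    times = schedule@nSeasons),
    last_day = rep(seq_len(perSeason) * aggregationDays,
                   times = schedule@nSeasons))
}

#' Build a three-state encounter history from event-level detections
#'
#' Pools the recorded days of each season into consecutive non-overlapping
#' surveys of \code{aggregationDays} days (blocks never span seasons) and
#' assigns each site-survey a code:
#' \itemize{
#'   \item unconfirmed surveys: 1 when the aggregated detection probability
#'     \code{q} (see [surveyDetectionProbability()]) meets or exceeds the
#'     threshold, else 0;
#'   \item confirmed surveys: every event-level detection is manually
#'     reviewed, so the code is 2 when the survey contains at least one true
#'     target signal, else 0 (all detections verified to be false alarms, or
#'     no detections at all). Confirmed surveys bypass the threshold.
#' }
#' Confirmation slots are drawn by [assignConfirmedSurveys()] over all
#' site-surveys, so a confirmed survey may well contain no events.
#'
#' @param events An [EventTable-class] with scores assigned.
#' @param occ The [OccupancyState-class] the events were generated from
#'   (fixes the site dimension; also used to validate consistency).
#' @param schedule The [RecordingSchedule-class] used for the events.
#' @param cfg An [AggregationConfig-class].
#' @param confirmed Optional pre-computed binary confirmation matrix; when
#'   \code{NULL} (default) one is drawn from \code{cfg@confirmProp}.
#' @return An [EncounterHistory-class].
#' @examples
#' set.seed(1)
#' occ <- simulateOccupancy(DynamicsParams(0.6, 0.25, 0.25), 25)
#' ev <- simulateSoundscape(occ, RecordingSchedule(), 20, 48,
#'                          goodClassifier())
#' eh <- buildEncounterHistory(ev, occ, RecordingSchedule(),
#'                             AggregationConfig(1, 0.95, 0.05))
#' @export
buildEncounterHistory <- function(events, occ, schedule, cfg,
                                  confirmed = NULL) {
  stopifnot(is(events, "EventTable"), is(occ, "OccupancyState"),
            is(schedule, "RecordingSchedule"), is(cfg, "AggregationConfig"))
  validObject(cfg)
  meta <- .surveyLayout(schedule, cfg@aggregationDays)
  ns <- nrow(occ@z)
  nSurv <- nrow(meta)
  perSeason <- nSurv %/% schedule@nSeasons

  ev <- events@events
  if (nrow(ev)) {
    if (anyNA(ev$score))
      stop("events must have scores assigned before aggregation")
    if (any(ev$day > schedule@daysPerSeason) ||
        any(ev$minute > schedule@minutesPerDay) ||
        any(ev$season > schedule@nSeasons) || any(ev$site_id > ns))
      stop("events fall outside the recording schedule")
  }

  if (is.null(confirmed))
    confirmed <- assignConfirmedSurveys(ns, nSurv, cfg@confirmProp)

  q <- matrix(0, ns, nSurv)
  hasTarget <- matrix(FALSE, ns, nSurv)
  if (nrow(ev)) {
    surveyOf <- (ev$season - 1L) * perSeason +
      (ev$day - 1L) %/% cfg@aggregationDays + 1L
    dt <- data.table::data.table(
      site = ev$site_id, survey = surveyOf,
      lc = log1p(-ev$score), tgt = ev$is_target)
    agg <- dt[, list(lsum = sum(lc), any_tgt = any(tgt == 1L)),
              by = c("site", "survey")]
    idx <- cbind(agg$site, agg$survey)
    q[idx] <- -expm1(agg$lsum)
    hasTarget[idx] <- agg$any_tgt
  }

  codes <- matrix(0L, ns, nSurv)
  codes[confirmed == 0L & q >= cfg@threshold] <- 1L
  codes[confirmed == 1L & hasTarget] <- 2L

  EncounterHistory(codes = codes, surveyMeta = meta,
                   confirmed = confirmed)
}

#' Survey-level true and false positive rates
#'
#' Compares an encounter history with the latent occupancy truth. The true
#' positive rate is the proportion of site-surveys at occupied site-seasons
#' whose code is 1 or 2; the false positive rate is the proportion of
#' site-surveys at unoccupied site-seasons whose code is 1 or 2 (code 2 is
#' impossible there). A rate with an empty denominator is returned as
#' \code{NA}.
#'
#' @param eh An [EncounterHistory-class].
#' @param occ The matching [OccupancyState-class].
#' @return A [RateSummary-class].
#' @export
computeSurveyRates <- function(eh, occ) {
  stopifnot(is(eh, "EncounterHistory"), is(occ, "OccupancyState"))
  if (nrow(eh@codes) != nrow(occ@z))
    stop("site dimensions of the history and occupancy state differ")
  season <- eh@surveyMeta$season
  if (max(season) > ncol(occ@z))
    stop("history refers to seasons missing from the occupancy state")
  occExp <- occ@z[, season, drop = FALSE]  # sites x surveys
  det <- eh@codes >= 1L
  nOcc <- sum(occExp == 1L)
  nUnocc <- sum(occExp == 0L)
  tp <- if (nOcc) sum(det & occExp == 1L) / nOcc else NA_real_
  fp <- if (nUnocc) sum(det & occExp == 0L) / nUnocc else NA_real_
  new("RateSummary", tpRate = tp, fpRate = fp,
      nOccupied = as.integer(nOcc), nUnoccupied = as.integer(nUnocc))
}
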