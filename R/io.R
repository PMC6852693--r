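#' Read and write event tables
#'
#' Event tables are stored as plain CSV with the header
#' \code{site_id,season,day,minute,is_target,score}. Scores are written at
#' full double precision so a write/read round trip is exact.
#'
#' @param events An [EventTable-class].
#' @param path File path.
#' @return \code{writeEventTable} returns \code{path} invisibly;
#'   \code{readEventTable} returns an [EventTable-class].
#' @export
writeEventTable <- function(events, path) {
  stopifnot(is(events, "EventTable"))
  ev <- events@events
  # shortest round-trip representation so read-back is bit-exact
  ev$score <- sprintf("%.17g", ev$score)
  data.table::fwrite(ev, path, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  ev <- as.data.frame(data.table::fread(path,
    colClasses = list(integer = c("site_id", "season", "day", "minute",
                                  "is_target"),
                      double = "score")))
  EventTable(events = ev)
}

#' Read and write encounter histories
#'
#' The code matrix is stored as CSV (\code{site_id} plus one
#' \code{survey_*} column per survey). A JSON sidecar file (same path with
#' extension \code{.meta.json}) carries the survey metadata
#' (season and day range per survey) and the confirmed mask.
#'
#' @param eh An [EncounterHistory-class].
#' @param path CSV file path; the sidecar path is derived from it.
#' @return \code{writeEncounterHistory} returns \code{path} invisibly;
#'   \code{readEncounterHistory} returns an [EncounterHistory-class].
#' @export
writeEncounterHistory <- function(eh, path) {
  stopifnot(is(eh, "EncounterHistory"))
  codes <- as.data.frame(eh@codes)
  names(codes) <- sprintf("survey_%d", seq_len(ncol(eh@codes)))
  df <- cbind(site_id = seq_len(nrow(eh@codes)), codes)
  data.table::fwrite(df, path)
  side <- list(survey_meta = eh@surveyMeta,
               confirmed = unname(apply(eh@confirmed, 1L, paste,
                                        collapse = "")))
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecarPath <- function(path) sub("\\.csv$", "", path) |>
  paste0(".meta.json")

#' @rdname writeEncounterHistory
#' @export
readEncounterHistory <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  codes <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(codes) <- NULL
  storage.mode(codes) <- "integer"
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  meta <- as.data.frame(side$survey_meta)
  conf <- do.call(rbind, lapply(strsplit(side$confirmed, ""), as.integer))
  EncounterHistory(codes = codes, surveyMeta = meta, confirmed = conf)
}

#' Write a model fit as JSON
#'
#' @param fit A [MillerFit-class].
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "MillerFit"))
  out <- list(estimates = as.list(as.numeric(fit@estimates)),
              neg_log_lik = fit@negLogLik,
              converged = fit@converged,
              n_iterations = fit@nIterations,
              grad_norm = fit@gradNorm,
              boundary_flags = as.list(fit@boundaryFlags))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.configDefaults <- function() {
  list(dynamics = "HH", psi = NULL, gamma = NULL, epsilon = NULL,
       lambda_c = 20, lambda_f = 48, classifier = "good",
       days_per_season = 30, minutes_per_day = 5, n_seasons = 2,
       aggregation_days = 1, threshold = 0.95, confirm_prop = 0.05,
       n_sites = 100, seed = 1, label = NULL)
}

#' Load a scenario configuration from YAML or JSON
#'
#' Reads a configuration file (format chosen by extension: \code{.yml} /
#' \code{.yaml} or \code{.json}) and returns a validated
#' [ScenarioConfig-class] with defaults filled in: two 30-day seasons,
#' 5 minutes of recording per day, 48 false alarms per hour, 100 sites,
#' the "HH" dynamics case, low call rate and the good classifier. A named
#' dynamics case (\code{dynamics: HL}) fills psi/gamma/epsilon, which can
#' also be given explicitly (explicit values win). Unknown keys and
#' out-of-range values are rejected with descriptive errors.
#'
#' @param path Path to the configuration file. An empty file yields the
#'   all-defaults configuration.
#' @return A [ScenarioConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("configuration must be a .yaml/.yml or .json file")
  if (is.null(raw)) raw <- list()
  defaults <- .configDefaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)

  dyn <- dynamicsScenario(cfg$dynamics)
  if (!is.null(cfg$psi)) dyn@psi <- cfg$psi
  if (!is.null(cfg$gamma)) dyn@gamma <- cfg$gamma
  if (!is.null(cfg$epsilon)) dyn@epsilon <- cfg$epsilon
  validObject(dyn)

  classifier <- switch(tolower(cfg$classifier),
                       good = goodClassifier(),
                       bad = badClassifier(),
                       stop("'classifier' must be \"good\" or \"bad\""))

  label <- cfg$label %||%
    sprintf("%s_c%g_%s_%dd_t%g_conf%g", toupper(cfg$dynamics),
            cfg$lambda_c, classifier@label, as.integer(cfg$aggregation_days),
            cfg$threshold, cfg$confirm_prop)

  ScenarioConfig(
    dynamics = dyn, lambdaC = cfg$lambda_c, lambdaF = cfg$lambda_f,
    classifier = classifier,
    schedule = RecordingSchedule(daysPerSeason = cfg$days_per_season,
                                 minutesPerDay = cfg$minutes_per_day,
                                 nSeasons = cfg$n_seasons),
    agg = AggregationConfig(aggregationDays = cfg$aggregation_days,
                            threshold = cfg$threshold,
                            confirmProp = cfg$confirm_prop),
    nSites = cfg$n_sites, seed = cfg$seed, label = label)
}

#' Deterministic two-survey worked example
#'
#' A tiny deterministic fixture: one site surveyed twice (1-day
#' aggregation), with three event-level detections per survey carrying
#' scores 0.15, 0.04, 0.11 (survey 1) and 0.56, 0.88, 0.71 (survey 2). The
#' aggregated detection probabilities are 0.2736 and ~0.9847, so at the
#' 0.95 survey-level threshold the expected encounter history is "01".
#'
#' @return A list with \code{events} (an [EventTable-class]),
#'   \code{schedule}, \code{occ} (single occupied site) and
#'   \code{expectedCodes} (the "01" history at threshold 0.95).
#' @examples
#' fx <- twoSurveyExample()
#' surveyDetectionProbability(eventData(fx$events)$score[1:3])
#' @export
twoSurveyExample <- function() {
  events <- EventTable(events = data.frame(
    site_id = 1L, season = 1L, day = rep(c(1L, 2L), each = 3L),
    minute = c(1L, 2L, 4L, 1L, 3L, 5L),
    is_target = c(0L, 0L, 0L, 1L, 1L, 1L),
    score = c(0.15, 0.04, 0.11, 0.56, 0.88, 0.71)))
  schedule <- RecordingSchedule(daysPerSeason = 2L, minutesPerDay = 5L,
                                nSeasons = 1L)
  occ <- OccupancyState(z = matrix(1L, 1L, 1L))
  list(events = events, schedule = schedule, occ = occ,
       expectedCodes = c(0L, 1L))
}
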