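#' Named dynamics scenarios
#'
#' The four canonical occupancy-dynamics cases used throughout the
#' simulation study: high/low initial occurrence crossed with high/low
#' turnover.
#'
#' @param name One of \code{"HH"} (psi = 0.60, gamma = epsilon = 0.25),
#'   \code{"HL"} (0.60, 0.05), \code{"LH"} (0.20, 0.25), \code{"LL"}
#'   (0.20, 0.05).
#' @return A [DynamicsParams-class].
#' @examples
#' dynamicsScenario("HH")
#' @export
dynamicsScenario <- function(name) {
  name <- match.arg(toupper(name), c("HH", "HL", "LH", "LL"))
  psi <- if (substr(name, 1L, 1L) == "H") 0.60 else 0.20
  turn <- if (substr(name, 2L, 2L) == "H") 0.25 else 0.05
  DynamicsParams(psi = psi, gamma = turn, epsilon = turn)
}

.MODULUS <- 2147483647  # 2^31 - 1; keeps derived seeds valid R integers

.scenarioSeed <- function(masterSeed, index) {
  as.integer((abs(masterSeed) %% .MODULUS * 100003 + index * 7907) %%
               .MODULUS + 1)
}

.replicateSeed <- function(scenarioSeed, rep) {
  as.integer(((scenarioSeed %% 65536) * 32749 + rep * 7919) %% .MODULUS + 1)
}

#' Construct the full simulation scenario grid
#'
#' Crosses the four dynamics cases, two call production rates, two
#' classifiers, two aggregation windows, two detection thresholds and two
#' confirmation proportions into the full 4 x 2 x 2 x 2 x 2 x 2 = 128
#' scenario grid. Any factor can be restricted through the arguments to
#' obtain a sub-grid.
#'
#' @param masterSeed Integer master seed; each scenario receives a seed
#'   derived deterministically from it, so sub-grids are reproducible
#'   independently of the rest of the grid.
#' @param dynamics Character vector of dynamics case names.
#' @param lambdaC Call rates per hour.
#' @param classifiers List of [ClassifierSpec-class] objects.
#' @param aggregationDays Aggregation windows in days.
#' @param thresholds Survey-level detection thresholds.
#' @param confirmProps Confirmation proportions.
#' @param nSites Sites per scenario.
#' @param schedule A [RecordingSchedule-class].
#' @param lambdaF False alarm rate per hour (shared by all scenarios).
#' @return A list of [ScenarioConfig-class] objects with descriptive
#'   labels such as \code{"HH_c20_good_1d_t0.95_conf0.05"}.
#' @examples
#' length(scenarioGrid(1))  # 128
#' @export
scenarioGrid <- function(masterSeed = 1L,
                         dynamics = c("HH", "HL", "LH", "LL"),
                         lambdaC = c(20, 100),
                         classifiers = list(goodClassifier(),
                                            badClassifier()),
                         aggregationDays = c(1L, 3L),
                         thresholds = c(0.80, 0.95),
                         confirmProps = c(0.025, 0.05),
                         nSites = 100L,
                         schedule = RecordingSchedule(),
                         lambdaF = 48) {
  grid <- expand.grid(conf = confirmProps, thr = thresholds,
                      agg = aggregationDays,
                      cls = seq_along(classifiers), lc = lambdaC,
                      dyn = dynamics, stringsAsFactors = FALSE)
  configs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cls <- classifiers[[g$cls]]
    label <- sprintf("%s_c%g_%s_%dd_t%g_conf%g", g$dyn, g$lc, cls@label,
                     g$agg, g$thr, g$conf)
    configs[[i]] <- ScenarioConfig(
      dynamics = dynamicsScenario(g$dyn), lambdaC = g$lc,
      lambdaF = lambdaF, classifier = cls, schedule = schedule,
      agg = AggregationConfig(aggregationDays = g$agg, threshold = g$thr,
                              confirmProp = g$conf),
      nSites = nSites, seed = .scenarioSeed(masterSeed, i), label = label)
  }
  configs
}

# realised survey-level detection parameters of one simulated data set;
# these are the marginal quantities the fitted p10/p11/b estimate
.realizedDetectionTruth <- function(eh, occ) {
  season <- eh@surveyMeta$season
  occExp <- occ@z[, season, drop = FALSE]
  codes <- eh@codes
  occIdx <- occExp == 1L
  det <- codes >= 1L
  nOcc <- sum(occIdx)
  nUnocc <- sum(!occIdx)
  p11 <- if (nOcc) sum(det[occIdx]) / nOcc else NA_real_
  p10 <- if (nUnocc) sum(det[!occIdx]) / nUnocc else NA_real_
  nDetOcc <- sum(det[occIdx])
  b <- if (nDetOcc) sum(codes[occIdx] == 2L) / nDetOcc else NA_real_
  c(p10 = p10, p11 = p11, b = b)
}

#' Run one simulation replicate end to end
#'
#' Executes the full pipeline for one scenario replicate: latent dynamics,
#' soundscape (calls, false alarms, classifier scores), encounter-history
#' aggregation, survey-rate summary, and the maximum-likelihood model fit
#' initialised at the generating state-parameter values (with the realised
#' survey-level detection rates as the informed detection starts).
#'
#' @param cfg A [ScenarioConfig-class].
#' @param repSeed Integer seed for this replicate; two runs with the same
#'   \code{cfg} and \code{repSeed} are identical.
#' @return A list with elements \code{fit} ([MillerFit-class]),
#'   \code{rates} ([RateSummary-class]) and \code{truth} (named vector of
#'   the six generating/realised parameter values).
#' @export
runReplicate <- function(cfg, repSeed) {
  stopifnot(is(cfg, "ScenarioConfig"))
  set.seed(as.integer(repSeed))
  occ <- simulateOccupancy(cfg@dynamics, cfg@nSites, cfg@schedule@nSeasons)
  ev <- simulateSoundscape(occ, cfg@schedule, cfg@lambdaC, cfg@lambdaF,
                           cfg@classifier)
  eh <- buildEncounterHistory(ev, occ, cfg@schedule, cfg@agg)
  rates <- computeSurveyRates(eh, occ)
  detTruth <- .realizedDetectionTruth(eh, occ)
  truth <- c(psi = cfg@dynamics@psi, gamma = cfg@dynamics@gamma,
             epsilon = cfg@dynamics@epsilon, detTruth)
  initDet <- ifelse(is.na(detTruth), 0.1, detTruth)
  init <- .vecToParams(pmin(pmax(
    c(truth[["psi"]], truth[["gamma"]], truth[["epsilon"]], initDet),
    0.01), 0.99))
  fit <- tryCatch(fitMillerModel(eh, init = init),
                  error = function(e) NULL)
  list(fit = fit, rates = rates, truth = truth)
}

#' Run a grid of scenarios with replication
#'
#' Runs \code{nReps} replicates of every scenario, one row per
#' (scenario, replicate). Replicate seeds are derived deterministically
#' from each scenario's seed and the replicate index, so any subset of the
#' grid is reproducible in isolation. A fit failure is recorded in its row,
#' never raised.
#'
#' @param configs List of [ScenarioConfig-class] objects (see
#'   [scenarioGrid()]), or a single config.
#' @param nReps Replicates per scenario.
#' @param verbose Print per-scenario progress lines.
#' @return A \code{data.frame} with scenario label and factors, replicate
#'   index and seed, convergence flag, negative log-likelihood, estimates
#'   (\code{est_*}), generating/realised truth (\code{true_*}), and
#'   survey-level rates (\code{tp_rate}, \code{fp_rate}).
#' @export
runScenarioGrid <- function(configs, nReps = 100L, verbose = FALSE) {
  if (is(configs, "ScenarioConfig")) configs <- list(configs)
  stopifnot(length(configs) >= 1L, nReps >= 1L)
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    if (verbose)
      message(sprintf("[%d/%d] %s (%d reps)", i, length(configs),
                      cfg@label, nReps))
    rows <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      sd <- .replicateSeed(cfg@seed, r)
      res <- runReplicate(cfg, sd)
      est <- if (is.null(res$fit)) rep(NA_real_, 6L)
             else as.numeric(estimates(res$fit))
      rows[[r]] <- data.frame(
        label = cfg@label, classifier = cfg@classifier@label,
        lambda_c = cfg@lambdaC,
        aggregation_days = cfg@agg@aggregationDays,
        threshold = cfg@agg@threshold,
        confirm_prop = cfg@agg@confirmProp,
        rep = r, seed = sd,
        converged = !is.null(res$fit) && converged(res$fit),
        neg_log_lik = if (is.null(res$fit)) NA_real_
                      else negLogLik(res$fit),
        est_psi = est[[1L]], est_gamma = est[[2L]],
        est_epsilon = est[[3L]], est_p10 = est[[4L]],
        est_p11 = est[[5L]], est_b = est[[6L]],
        true_psi = res$truth[["psi"]], true_gamma = res$truth[["gamma"]],
        true_epsilon = res$truth[["epsilon"]],
        true_p10 = res$truth[["p10"]], true_p11 = res$truth[["p11"]],
        true_b = res$truth[["b"]],
        tp_rate = tpRate(res$rates), fp_rate = fpRate(res$rates))
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise estimator bias per scenario
#'
#' Computes raw bias (estimate minus truth) for every parameter and
#' replicate, then its mean and standard deviation per scenario over the
#' converged replicates only. Scenarios with zero converged replicates get
#' \code{NA} summaries.
#'
#' @param results Result table from [runScenarioGrid()].
#' @return A \code{data.frame} with one row per scenario x parameter:
#'   \code{label}, \code{parameter}, \code{mean_bias}, \code{sd_bias},
#'   \code{n_converged}, \code{n_replicates}, \code{convergence_rate}.
#' @export
summarizeBias <- function(results) {
  need <- c("label", "converged",
             paste0("est_", .paramNames), paste0("true_", .paramNames))
  if (!all(need %in% names(results)))
    stop("'results' does not look like a runScenarioGrid() table")
  dt <- data.table::as.data.table(results)
  pieces <- lapply(.paramNames, function(p) {
    d <- dt[, list(
      parameter = p,
      mean_bias = {
        b <- get(paste0("est_", p))[converged] -
          get(paste0("true_", p))[converged]
        if (length(b)) mean(b, na.rm = TRUE) else NA_real_
      },
      sd_bias = {
        b <- get(paste0("est_", p))[converged] -
          get(paste0("true_", p))[converged]
        if (length(b) > 1L) stats::sd(b, na.rm = TRUE) else NA_real_
      },
      n_converged = sum(converged),
      n_replicates = .N), by = "label"]
    d
  })
  summ <- data.table::rbindlist(pieces)
  summ[, "convergence_rate" := summ$n_converged / summ$n_replicates]
  data.table::setorderv(summ, c("label", "parameter"))
  as.data.frame(summ)
}
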