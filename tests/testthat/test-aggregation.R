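test_that("survey detection probability is the complement product", {
  expect_equal(surveyDetectionProbability(c(0.15, 0.04, 0.11)),
               1 - 0.85 * 0.96 * 0.89)
  expect_equal(surveyDetectionProbability(c(0.56, 0.88, 0.71)),
               1 - 0.44 * 0.12 * 0.29)
  expect_equal(surveyDetectionProbability(numeric(0)), 0)
  expect_equal(surveyDetectionProbability(0.5), 0.5)
  expect_error(surveyDetectionProbability(c(0.2, 1.3)), "probabilities")
  expect_error(surveyDetectionProbability(c(-0.1)), "probabilities")
})

test_that("q is monotone in appended events and stays in [0, 1]", {
  set.seed(5)
  for (i in 1:20) {
    sc <- runif(sample(0:8, 1))
    q <- surveyDetectionProbability(sc)
    expect_gte(q, 0)
    expect_lte(q, 1)
    extra <- runif(1, 0.01, 0.99)
    expect_gt(surveyDetectionProbability(c(sc, extra)), q)
  }
})

test_that("confirmation selects floor(prop * units) site-surveys", {
  set.seed(6)
  expect_equal(sum(assignConfirmedSurveys(100, 60, 0.05)), 300)
  expect_equal(sum(assignConfirmedSurveys(100, 60, 0.025)), 150)
  expect_equal(sum(assignConfirmedSurveys(10, 7, 0)), 0)
  expect_equal(sum(assignConfirmedSurveys(10, 7, 1)), 70)
  # flooring never exceeds the budget
  expect_equal(sum(assignConfirmedSurveys(7, 9, 0.5)), 31)
})

test_that("the worked two-survey example aggregates to the right codes", {
  fx <- twoSurveyExample()
  noConf <- matrix(0L, 1, 2)
  codesAt <- function(thr) {
    eh <- buildEncounterHistory(fx$events, fx$occ, fx$schedule,
                                AggregationConfig(1, thr, 0),
                                confirmed = noConf)
    as.vector(encounterCodes(eh))
  }
  expect_equal(codesAt(0.95), c(0L, 1L))   # q = 0.274, 0.985
  expect_equal(codesAt(0.20), c(1L, 1L))
  expect_equal(codesAt(0.99), c(0L, 0L))
})

test_that("survey blocks partition each season in schedule order", {
  set.seed(7)
  occ <- simulateOccupancy(DynamicsParams(0.6, 0.25, 0.25), 10)
  sch <- RecordingSchedule()
  ev <- simulateSoundscape(occ, sch, 20, 48, goodClassifier())

  eh1 <- buildEncounterHistory(ev, occ, sch, AggregationConfig(1, 0.95, 0))
  expect_equal(nSurveys(eh1), 60)
  eh3 <- buildEncounterHistory(ev, occ, sch, AggregationConfig(3, 0.95, 0))
  expect_equal(nSurveys(eh3), 20)
  m <- surveyMeta(eh3)
  expect_equal(m$season, rep(1:2, each = 10))
  expect_equal(m$first_day, rep(seq(1, 28, by = 3), 2))
  expect_equal(m$last_day, m$first_day + 2)

  # 7-day blocks do not divide a 30-day season
  expect_error(buildEncounterHistory(ev, occ, sch,
                                     AggregationConfig(7, 0.95, 0)),
               "divide")
})

test_that("no events anywhere gives an all-zero history", {
  occ <- OccupancyState(z = matrix(c(1L, 0L), 4, 2))
  eh <- buildEncounterHistory(EventTable(), occ, RecordingSchedule(),
                              AggregationConfig(3, 0.8, 0.05))
  expect_true(all(encounterCodes(eh) == 0L))
  r <- computeSurveyRates(eh, occ)
  expect_equal(tpRate(r), 0)
  expect_equal(fpRate(r), 0)
})

test_that("code 2 occurs only at confirmed, occupied site-surveys", {
  set.seed(8)
  occ <- simulateOccupancy(DynamicsParams(0.5, 0.25, 0.25), 50)
  sch <- RecordingSchedule()
  ev <- simulateSoundscape(occ, sch, 100, 48, badClassifier())
  eh <- buildEncounterHistory(ev, occ, sch,
                              AggregationConfig(1, 0.8, 0.2))
  codes <- encounterCodes(eh)
  conf <- confirmedMask(eh)
  occExp <- occupancyMatrix(occ)[, surveyMeta(eh)$season]
  expect_true(all(conf[codes == 2L] == 1L))
  expect_true(all(occExp[codes == 2L] == 1L))
  # confirmed surveys never produce uncertain (code 1) detections
  expect_true(all(codes[conf == 1L] %in% c(0L, 2L)))
})

test_that("raising the threshold never adds code-1 surveys", {
  set.seed(9)
  occ <- simulateOccupancy(DynamicsParams(0.5, 0.25, 0.25), 30)
  sch <- RecordingSchedule()
  ev <- simulateSoundscape(occ, sch, 20, 48, goodClassifier())
  conf <- assignConfirmedSurveys(30, 60, 0.05)
  n1 <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99, 1.0), function(thr) {
    eh <- buildEncounterHistory(ev, occ, sch,
                                AggregationConfig(1, thr, 0.05),
                                confirmed = conf)
    sum(encounterCodes(eh) == 1L)
  }, numeric(1))
  expect_true(all(diff(n1) <= 0))

  # continuous scores are < 1 almost surely, so threshold 1 kills all
  # uncertain detections and the false positive rate is exactly 0
  eh1 <- buildEncounterHistory(ev, occ, sch, AggregationConfig(1, 1, 0.05),
                               confirmed = conf)
  expect_equal(fpRate(computeSurveyRates(eh1, occ)), 0)
})

test_that("survey rates use the right denominators and flag empty ones", {
  # hand-built 2-site, 2-survey case: site 1 occupied both seasons
  occ <- OccupancyState(z = matrix(c(1L, 0L, 1L, 0L), 2, 2))
  meta <- data.frame(survey = 1:2, season = 1:2, first_day = 1L,
                     last_day = 30L)
  codes <- matrix(c(1L, 1L, 0L, 0L), 2, 2)  # site1: 1,0; site2: 1,0
  eh <- new("EncounterHistory", codes = codes, surveyMeta = meta,
            confirmed = matrix(0L, 2, 2))
  r <- computeSurveyRates(eh, occ)
  expect_equal(tpRate(r), 0.5)  # site 1 detected in 1 of 2 surveys
  expect_equal(fpRate(r), 0.5)  # site 2 mistakenly detected in 1 of 2

  allOcc <- OccupancyState(z = matrix(1L, 2, 2))
  expect_true(is.na(fpRate(computeSurveyRates(eh, allOcc))))
})
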