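test_that("observation probabilities match the factorisation and normalise", {
  p <- MillerParams(p10 = 0.1, p11 = 0.8, b = 0.25)
  expect_equal(surveyObservationProbability(0:2, TRUE, p),
               c(0.2, 0.6, 0.2))
  expect_equal(surveyObservationProbability(0:2, FALSE, p),
               c(0.9, 0.1, 0))
  expect_equal(surveyObservationProbability(2, FALSE, randomMillerParams()),
               0)

  set.seed(10)
  for (i in 1:25) {
    q <- randomMillerParams()
    expect_equal(sum(surveyObservationProbability(0:2, TRUE, q)), 1)
    expect_equal(sum(surveyObservationProbability(0:2, FALSE, q)), 1)
  }
})

test_that("single-survey site likelihoods have their closed forms", {
  p <- MillerParams(psi = 0.6, gamma = 0.25, epsilon = 0.25,
                    p10 = 0.1, p11 = 0.5, b = 0.3)
  expect_equal(siteHistoryLikelihood(0L, 1L, p),
               (1 - 0.6) * (1 - 0.1) + 0.6 * (1 - 0.5))
  expect_equal(siteHistoryLikelihood(2L, 1L, p), 0.6 * 0.5 * 0.3)
  expect_equal(siteHistoryLikelihood(1L, 1L, p),
               (1 - 0.6) * 0.1 + 0.6 * 0.5 * 0.7)
})

test_that("forward recursion agrees with brute-force enumeration", {
  p <- MillerParams(psi = 0.6, gamma = 0.25, epsilon = 0.25,
                    p10 = 0.1, p11 = 0.5, b = 0.3)
  # the two-season worked history 120|000
  codes <- c(1L, 2L, 0L, 0L, 0L, 0L)
  season <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(siteHistoryLikelihood(codes, season, p),
               bruteForceSiteLik(codes, season, 0.6, 0.25, 0.25,
                                 0.1, 0.5, 0.3),
               tolerance = 1e-12)

  # random small instances, including >2 seasons
  set.seed(11)
  for (i in 1:8) {
    S <- sample(1:3, 1)
    perSeason <- sample(1:3, 1)
    season <- rep(seq_len(S), each = perSeason)
    codes <- sample(0:2, length(season), replace = TRUE)
    q <- randomMillerParams()
    v <- as.numeric(q)
    expect_equal(
      siteHistoryLikelihood(codes, season, q),
      bruteForceSiteLik(codes, season, v[["psi"]], v[["gamma"]],
                        v[["epsilon"]], v[["p10"]], v[["p11"]],
                        v[["b"]]),
      tolerance = 1e-12)
  }
})

test_that("likelihood sums to one over the full history sample space", {
  set.seed(12)
  season <- c(1L, 1L, 2L, 2L)
  hist4 <- allHistories(4)
  for (i in 1:3) {
    p <- randomMillerParams()
    tot <- sum(apply(hist4, 1, function(h) {
      exp(-millerNegLogLik(matrix(as.integer(h), 1), p, season = season))
    }))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("negative log-likelihood adds over sites and flags impossibility", {
  p <- MillerParams(psi = 0.6, gamma = 0.25, epsilon = 0.25,
                    p10 = 0.1, p11 = 0.5, b = 0.3)
  season <- c(1L, 1L, 2L, 2L)
  codes <- matrix(c(1L, 0L, 0L, 2L,
                    0L, 0L, 0L, 0L), 2, 4, byrow = TRUE)
  nll <- millerNegLogLik(codes, p, season = season)
  l1 <- siteHistoryLikelihood(codes[1, ], season, p)
  l2 <- siteHistoryLikelihood(codes[2, ], season, p)
  expect_equal(nll, -(log(l1) + log(l2)))

  # code 2 with b = 0 is impossible data
  p0 <- MillerParams(psi = 0.6, gamma = 0.25, epsilon = 0.25,
                     p10 = 0.1, p11 = 0.5, b = 0)
  expect_equal(siteHistoryLikelihood(2L, 1L, p0), 0)
  expect_equal(millerNegLogLik(matrix(2L, 1, 1), p0, season = 1L), Inf)
})

test_that("the maximum-likelihood fit recovers generating parameters", {
  set.seed(13)
  truth <- DynamicsParams(0.6, 0.25, 0.25)
  occ <- simulateOccupancy(truth, 500)
  sch <- RecordingSchedule()
  ev <- simulateSoundscape(occ, sch, 20, 48, goodClassifier())
  eh <- buildEncounterHistory(ev, occ, sch,
                              AggregationConfig(1, 0.95, 0.05))
  init <- MillerParams(psi = 0.6, gamma = 0.25, epsilon = 0.25,
                       p10 = 0.05, p11 = 0.6, b = 0.05)
  fit <- fitMillerModel(eh, init = init)
  expect_true(converged(fit))
  est <- as.numeric(estimates(fit))
  expect_lt(abs(est[["psi"]] - 0.6), 0.05)
  expect_lt(abs(est[["gamma"]] - 0.25), 0.05)
  expect_lt(abs(est[["epsilon"]] - 0.25), 0.05)

  # the optimum is no worse than the truth-anchored start or perturbations
  nllInit <- millerNegLogLik(eh, init)
  expect_lte(negLogLik(fit), nllInit)
})

test_that("degenerate all-zero histories hit the psi boundary, flagged", {
  meta <- data.frame(survey = 1:4, season = c(1, 1, 2, 2),
                     first_day = c(1, 16, 1, 16), last_day = c(15, 30, 15, 30))
  eh <- new("EncounterHistory", codes = matrix(0L, 20, 4),
            surveyMeta = meta, confirmed = matrix(0L, 20, 4))
  fit <- fitMillerModel(eh)
  expect_false(converged(fit))
  expect_true(any(boundaryFlags(fit)))
  expect_lt(as.numeric(estimates(fit))[["psi"]], 0.05)
})

test_that("logit-scale optimisation reports the probability-scale NLL", {
  set.seed(14)
  occ <- simulateOccupancy(DynamicsParams(0.6, 0.25, 0.25), 60)
  sch <- RecordingSchedule()
  ev <- simulateSoundscape(occ, sch, 20, 48, goodClassifier())
  eh <- buildEncounterHistory(ev, occ, sch, AggregationConfig(1, 0.95, 0.05))
  fit <- fitMillerModel(eh)
  expect_equal(negLogLik(fit), millerNegLogLik(eh, estimates(fit)))
})
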