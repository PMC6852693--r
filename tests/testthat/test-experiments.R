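test_that("the full scenario grid enumerates 128 distinct scenarios", {
  grid <- scenarioGrid(1)
  expect_length(grid, 128)
  labels <- vapply(grid, function(g) g@label, character(1))
  expect_equal(anyDuplicated(labels), 0L)
  # factor counts: 4 dynamics x 2 call rates x 2 classifiers x 2 windows
  # x 2 thresholds x 2 confirmation levels
  expect_equal(sum(grepl("^HH_", labels)), 32)
  expect_equal(sum(grepl("_c100_", labels)), 64)
  expect_equal(sum(grepl("_bad_", labels)), 64)
  expect_equal(sum(grepl("_3d_", labels)), 64)
  expect_equal(sum(grepl("_t0.95_", labels)), 64)
  expect_equal(sum(grepl("_conf0.05$", labels)), 64)
})

test_that("replicates are reproducible and independent of grid position", {
  cfg <- scenarioGrid(3)[[5]]
  a <- runReplicate(cfg, 777)
  b <- runReplicate(cfg, 777)
  expect_identical(as.numeric(estimates(a$fit)),
                   as.numeric(estimates(b$fit)))
  expect_identical(a$truth, b$truth)
  expect_identical(tpRate(a$rates), tpRate(b$rates))
})

test_that("runScenarioGrid returns one row per scenario-replicate", {
  cfg <- ScenarioConfig(
    dynamics = dynamicsScenario("HH"), lambdaC = 100,
    schedule = RecordingSchedule(daysPerSeason = 6L),
    agg = AggregationConfig(1, 0.95, 0.05), nSites = 20L, seed = 11L,
    label = "tiny")
  res <- runScenarioGrid(cfg, nReps = 3)
  expect_equal(nrow(res), 3)
  expect_equal(res$label, rep("tiny", 3))
  expect_false(anyNA(res$est_psi[res$converged]))
  # deterministic seeds: rerun matches
  res2 <- runScenarioGrid(cfg, nReps = 3)
  expect_equal(res, res2)
})

test_that("bias summaries average estimate minus truth over converged fits", {
  fake <- data.frame(
    label = rep(c("A", "B"), each = 4),
    converged = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    est_psi = c(0.6, 0.6, 0.6, 9), est_gamma = c(0.3, 0.2, 0.25, 9),
    est_epsilon = 0.25, est_p10 = 0.1, est_p11 = 0.5, est_b = 0.1,
    true_psi = 0.6, true_gamma = 0.25, true_epsilon = 0.25,
    true_p10 = 0.1, true_p11 = 0.5, true_b = 0.1)
  s <- summarizeBias(fake)
  a <- s[s$label == "A", ]
  expect_equal(a$mean_bias[a$parameter == "psi"], 0)
  expect_equal(a$sd_bias[a$parameter == "psi"], 0)
  expect_equal(a$mean_bias[a$parameter == "gamma"], 0, tolerance = 1e-12)
  expect_equal(a$n_converged[1], 3)
  expect_equal(a$convergence_rate[1], 0.75)
  # non-converged replicate (est 9) is excluded everywhere
  expect_true(all(abs(s$mean_bias) < 1))

  # invariant to row order
  s2 <- summarizeBias(fake[sample(nrow(fake)), ])
  expect_equal(s, s2)
})

test_that("zero converged replicates flag the summary as missing", {
  fake <- data.frame(
    label = "Z", converged = FALSE,
    est_psi = 0.5, est_gamma = 0.2, est_epsilon = 0.2, est_p10 = 0.1,
    est_p11 = 0.5, est_b = 0.1, true_psi = 0.5, true_gamma = 0.2,
    true_epsilon = 0.2, true_p10 = 0.1, true_p11 = 0.5, true_b = 0.1)
  s <- summarizeBias(fake)
  expect_true(all(is.na(s$mean_bias)))
  expect_equal(unique(s$n_converged), 0L)
})

test_that("dynamics cases carry their canonical parameter values", {
  expect_equal(as.numeric(dynamicsScenario("HH")),
               c(psi = 0.60, gamma = 0.25, epsilon = 0.25))
  expect_equal(as.numeric(dynamicsScenario("HL")),
               c(psi = 0.60, gamma = 0.05, epsilon = 0.05))
  expect_equal(as.numeric(dynamicsScenario("LH")),
               c(psi = 0.20, gamma = 0.25, epsilon = 0.25))
  expect_equal(as.numeric(dynamicsScenario("LL")),
               c(psi = 0.20, gamma = 0.05, epsilon = 0.05))
})
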