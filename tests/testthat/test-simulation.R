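test_that("relativeChange and meanAbsoluteError match their definitions", {
  expect_equal(relativeChange(c(20, 25)), 25)
  expect_equal(relativeChange(c(15, 20, 50)), c(100 / 3, 150))
  expect_error(relativeChange(5), "two values")
  expect_error(relativeChange(c(0, 5)), "nonpositive")

  expect_equal(meanAbsoluteError(c(3, 5), c(5, 5)), 1)
  expect_equal(meanAbsoluteError(1:3, 1:3), 0)
  expect_error(meanAbsoluteError(1:2, 1:3), "length mismatch")
  expect_error(meanAbsoluteError(numeric(), numeric()), "at least one")
})

test_that("simulationConfig defaults encode the study conditions", {
  cfg <- simulationConfig()
  expect_equal(cfg@tvfLevelsPercent, seq(15, 80, 5))
  expect_equal(cfg@t2LongTrueMs, c(100, 150, 200))
  expect_equal(cfg@t2ShortTrueMs, 30)
  expect_equal(cfg@snr, 100)
  expect_identical(cfg@nAvg, 9L)
  expect_identical(cfg@nTrials, 1000L)
  expect_equal(cfg@constraints@t2LongFixedMs, 150)
  expect_identical(cfg@protocol@nEchoes, 13L)
  expect_equal(cfg@protocol@refocusingFlipDeg, 170)
  expect_error(simulationConfig(tvfLevelsPercent = c(50, 20)),
               "strictly increasing")
  expect_error(simulationConfig(snr = -1), "snr")
})

test_that("a noiseless trial recovers the true TVF when the model is correct", {
  cfg <- simulationConfig(tvfLevelsPercent = c(20, 50, 80),
                          t2LongTrueMs = 150, snr = Inf,
                          protocol = protocolPreset("short_te",
                                                    refocusingFlipDeg = 180),
                          nTrials = 1L, nAvg = 1L)
  for (lv in c(20, 50, 80))
    expect_equal(runTrial(cfg, 150, lv), lv, tolerance = 1e-3)
  # both averaging modes coincide without noise
  expect_equal(runTrial(cfg, 150, 50, avgMode = "signals"),
               runTrial(cfg, 150, 50, avgMode = "fits"), tolerance = 1e-6)
})

test_that("runTable2 is deterministic in the seed and reports all columns", {
  cfg <- simulationConfig(tvfLevelsPercent = c(40, 50), t2LongTrueMs = 150,
                          nTrials = 25L, rngSeed = 123L)
  a <- as.data.frame(runTable2(cfg))
  b <- as.data.frame(runTable2(cfg))
  expect_equal(a, b)
  expect_named(a, c("t2_long_true_ms", "tvf_true_percent",
                    "rel_change_true_percent", "tvf_mean_percent",
                    "tvf_sd_percent", "rel_change_mean_percent",
                    "rel_change_mae_percent"))
  expect_identical(nrow(a), 2L)
  expect_true(is.na(a$rel_change_mean_percent[1]))
  expect_equal(a$rel_change_true_percent[2], 25)
  expect_gte(attr(a, "nRegenerated"), 0L)

  cfg2 <- simulationConfig(tvfLevelsPercent = c(40, 50), t2LongTrueMs = 150,
                           nTrials = 25L, rngSeed = 124L)
  c2 <- as.data.frame(runTable2(cfg2))
  expect_false(isTRUE(all.equal(a$tvf_mean_percent, c2$tvf_mean_percent)))
})

test_that("averaging nine fits shrinks the trial variance about ninefold", {
  base <- list(tvfLevelsPercent = 50, t2LongTrueMs = 150, nTrials = 800L,
               rngSeed = 2024L)
  sd9 <- as.data.frame(runTable2(do.call(simulationConfig,
                                         c(base, nAvg = 9L))))$tvf_sd_percent
  sd1 <- as.data.frame(runTable2(do.call(simulationConfig,
                                         c(base, nAvg = 1L))))$tvf_sd_percent
  ratio <- (sd9 / sd1)^2
  # a priori band: +-30 % around 1/9 (relative SE of the variance ratio
  # with 800 trials is about 7 %)
  expect_gt(ratio, 1 / 9 * 0.7)
  expect_lt(ratio, 1 / 9 * 1.3)
})

test_that("the echo-train T1 values are not critical for the TVF estimate", {
  mk <- function(t1s, t1l)
    simulationConfig(tvfLevelsPercent = 50, t2LongTrueMs = 150, snr = Inf,
                     nTrials = 1L, nAvg = 1L, t1ShortMs = t1s, t1LongMs = t1l)
  ref <- runTrial(mk(1500, 2500), 150, 50)
  lo <- runTrial(mk(750, 1250), 150, 50)
  hi <- runTrial(mk(2250, 3750), 150, 50)
  expect_lt(abs(lo - ref), 0.5)
  expect_lt(abs(hi - ref), 0.5)
})

test_that("fixing the long T2 at the wrong value biases the absolute TVF", {
  # reduced-size check of the study's central effect at truth 50 %
  mk <- function(t2true)
    simulationConfig(tvfLevelsPercent = 50, t2LongTrueMs = t2true,
                     nTrials = 150L, rngSeed = 7L)
  under <- as.data.frame(runTable2(mk(200)))$tvf_mean_percent
  corr <- as.data.frame(runTable2(mk(150)))$tvf_mean_percent
  over <- as.data.frame(runTable2(mk(100)))$tvf_mean_percent
  expect_gt(under, 55)   # overestimation when true long T2 > fixed value
  expect_lt(over, 40)    # underestimation when true long T2 < fixed value
  expect_lt(abs(corr - 50), 2)
})
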