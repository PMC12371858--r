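test_that("phantomSpec defaults and validation", {
  spec <- phantomSpec()
  expect_equal(unname(spec@tvfPercent), c(29.8, 42.6, 76.4))
  expect_equal(unname(spec@t2ShortMs), c(38, 35, 30))
  expect_equal(spec@t2LongMs, 150)
  expect_identical(spec@gridSize, c(96L, 96L))
  expect_error(phantomSpec(gridSize = c(8L, 8L)), "at least 16")
  expect_error(phantomSpec(tvfPercent = c(cortex = 0, outer_medulla = 40,
                                          inner_medulla = 70)),
               "in \\(0, 100\\)")
  expect_error(phantomSpec(snr = -1), "snr")
})

test_that("generateLayeredImage produces disjoint layers with exact truth maps", {
  spec <- phantomSpec(gridSize = c(48L, 48L), snr = Inf)
  ph <- generateLayeredImage(spec)
  lab <- ph$labels@labels
  expect_true(all(lab %in% 0:3))
  expect_true(all(vapply(1:3, function(l) sum(lab == l) > 0, logical(1))))
  # truth maps carry the per-layer constants
  for (l in 1:3) {
    expect_true(all(mapValues(ph$truthTvf)[lab == l] == spec@tvfPercent[l]))
    expect_true(all(mapValues(ph$truthT2Short)[lab == l] == spec@t2ShortMs[l]))
  }
  # mask equals the union of the layers; background voxels are zero signal
  expect_identical(ph$image@mask, lab > 0L)
  expect_true(all(ph$image@data[rep(lab == 0L, 13)] == 0))
  # noiseless voxel equals the composed EPG signal of its layer
  v <- which(lab == 3L, arr.ind = TRUE)[1, ]
  f <- spec@tvfPercent[3] / 100
  expected <- spec@m0 *
    (f * epgEchoAmplitudes(150, spec@t1LongMs, spec@protocol) +
       (1 - f) * epgEchoAmplitudes(spec@t2ShortMs[3], spec@t1ShortMs,
                                   spec@protocol))
  expect_equal(as.numeric(ph$image@data[v[1], v[2], ]), expected,
               tolerance = 1e-12)
})

test_that("phantom generation is deterministic in the seed", {
  s1 <- generateLayeredImage(phantomSpec(gridSize = c(32L, 32L), rngSeed = 5L))
  s2 <- generateLayeredImage(phantomSpec(gridSize = c(32L, 32L), rngSeed = 5L))
  s3 <- generateLayeredImage(phantomSpec(gridSize = c(32L, 32L), rngSeed = 6L))
  expect_identical(s1$image@data, s2$image@data)
  expect_false(identical(s1$image@data, s3$image@data))
})

test_that("generateMixtureSeries returns fraction-true mixtures", {
  fr <- c(0, 0.25, 0.5, 1)
  ms <- generateMixtureSeries(fr, snr = Inf,
                              protocol = protocolPreset("short_te",
                                                        refocusingFlipDeg = 180))
  expect_equal(ms$tvfTruthPercent, 100 * fr)
  te <- echoTimes(protocolPreset("short_te"))
  expect_equal(signalAmplitude(ms$signals[[4]]), exp(-te / 150))
  expect_equal(signalAmplitude(ms$signals[[1]]), exp(-te / 30))
  expect_error(generateMixtureSeries(c(-0.1, 0.5)), "fractions")
})

test_that("interventionProfile and generateInterventionSeries are consistent", {
  pr <- interventionProfile()
  expect_identical(dim(pr@multipliers), c(3L, 11L))
  expect_true(all(pr@multipliers[, pr@baselineIdx] == 1))
  expect_equal(pr@multipliers["cortex", pr@interval1Idx], rep(1.311, 4))
  expect_identical(pr@interval2Idx, 9:11)

  spec <- phantomSpec(gridSize = c(24L, 24L), snr = Inf)
  series <- generateInterventionSeries(spec, pr)
  expect_length(series$frames, 11)
  # baseline frames carry the unscaled truth, interval frames the scaled one
  expect_equal(unname(roiMedian(series$frames[[1]]$truthTvf, series$labels)),
               unname(spec@tvfPercent))
  expect_equal(unname(roiMedian(series$frames[[5]]$truthTvf, series$labels)),
               unname(spec@tvfPercent * c(1.311, 1.307, 1.088)))
  # overshooting multipliers are rejected
  bad <- interventionProfile(interval1Effect = c(cortex = 4,
                                                 outer_medulla = 1,
                                                 inner_medulla = 1))
  expect_error(generateInterventionSeries(spec, bad), ">= 100")
})
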