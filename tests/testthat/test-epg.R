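test_that("EPG at 180 deg refocusing reduces exactly to mono-exponential decay", {
  p <- protocolPreset("short_te", refocusingFlipDeg = 180)
  for (t2 in c(30, 100, 150)) {
    amp <- epgEchoAmplitudes(t2, 1500, p)
    expect_lt(max(abs(amp - exp(-echoTimes(p) / t2))), 1e-12)
  }
  l <- protocolPreset("long_te")
  expect_lt(max(abs(epgEchoAmplitudes(80, 2000, l) -
                      exp(-echoTimes(l) / 80))), 1e-12)
})

test_that("EPG matches the independent isochromat Bloch oracle at imperfect flips", {
  p0 <- protocolPreset("short_te")
  for (flip in c(120, 150, 170, 180)) {
    p <- protocolPreset("short_te", refocusingFlipDeg = flip)
    epg <- epgEchoAmplitudes(30, 1500, p)
    bloch <- blochEchoAmplitudes(30, 1500, p, nSpins = 10000L)
    expect_lt(max(abs(epg - bloch)), 1e-4)
  }
  # also with a long-T2 compartment where T1 storage matters more
  epg <- epgEchoAmplitudes(150, 2500, p0)
  bloch <- blochEchoAmplitudes(150, 2500, p0, nSpins = 10000L)
  expect_lt(max(abs(epg - bloch)), 1e-4)
})

test_that("imperfect refocusing perturbs the echo train away from pure T2 decay", {
  p <- protocolPreset("short_te")  # 170 deg
  amp <- epgEchoAmplitudes(30, 1500, p)
  mono <- exp(-echoTimes(p) / 30)
  expect_true(all(amp > 0))
  expect_true(all(diff(amp) < 0))          # still monotone decaying
  expect_gt(max(abs(amp - mono)), 1e-3)    # the flip angle matters
  # the relative deviation grows along the train as stimulated-echo
  # pathways accumulate
  expect_gt(abs(amp[13] / mono[13] - 1), abs(amp[1] / mono[1] - 1))
})

test_that("composeSignal is the weight-linear combination of compartments", {
  p <- protocolPreset("short_te", refocusingFlipDeg = 180)
  cs <- compartmentSet(c(150, 30), c(0.5, 0.5), c(2500, 1500))
  s <- composeSignal(cs, p)
  te <- echoTimes(p)
  expect_equal(signalAmplitude(s),
               0.5 * exp(-te / 150) + 0.5 * exp(-te / 30), tolerance = 1e-12)
  # closed form at the first echo: 0.5 e^{-6.4/150} + 0.5 e^{-6.4/30}
  expect_equal(signalAmplitude(s)[1],
               0.5 * exp(-6.4 / 150) + 0.5 * exp(-6.4 / 30),
               tolerance = 1e-12)

  # m0 scales linearly
  cs2 <- compartmentSet(c(150, 30), c(0.5, 0.5), c(2500, 1500), m0 = 1000)
  expect_equal(signalAmplitude(composeSignal(cs2, p)),
               1000 * signalAmplitude(s))

  # MGE protocol: mono-exponential FID sampling, no refocusing dynamics
  g <- protocolPreset("mge")
  sg <- composeSignal(compartmentSet(12, 1, 1500), g)
  expect_equal(signalAmplitude(sg), exp(-echoTimes(g) / 12))
})

test_that("addGaussianNoise follows the sigma = mean(signal)/SNR convention", {
  p <- protocolPreset("long_te")
  s <- composeSignal(compartmentSet(c(150, 30), c(0.5, 0.5), c(2500, 1500)), p)
  sigma <- mean(signalAmplitude(s)) / 100

  # reproducible with a seed, and the caller's RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  n1 <- addGaussianNoise(s, 100, rngSeed = 7)
  n2 <- addGaussianNoise(s, 100, rngSeed = 7)
  expect_identical(signalAmplitude(n1), signalAmplitude(n2))
  expect_equal(runif(1), before)

  # empirical noise SD and mean over many draws
  eps <- replicate(400, signalAmplitude(addGaussianNoise(s, 100)) -
                          signalAmplitude(s))
  expect_equal(sd(as.vector(eps)), sigma, tolerance = 0.05)
  expect_lt(abs(mean(eps)), 3 * sigma / sqrt(length(eps)))

  # Inf SNR is a no-op; invalid SNR rejected
  expect_identical(signalAmplitude(addGaussianNoise(s, Inf)),
                   signalAmplitude(s))
  expect_error(addGaussianNoise(s, 0), "positive")
  expect_error(addGaussianNoise(s, -5), "positive")
})

test_that("EPG input validation rejects non-physical parameters", {
  p <- protocolPreset("short_te")
  expect_error(epgEchoAmplitudes(-1, 1500, p), "t2Ms")
  expect_error(epgEchoAmplitudes(30, 0, p), "t1Ms")
  expect_error(epgEchoAmplitudes(30, 1500, protocolPreset("mge")),
               "MESEProtocol")
})
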