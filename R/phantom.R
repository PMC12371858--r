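#' Specify a layered digital kidney phantom
#'
#' Nested elliptical layers (cortex ring, outer-medulla ring, inner-medulla
#' core) on a rectangular grid. Default per-layer TVFs are the baseline
#' in vivo layer values (cortex 29.8 %, outer medulla 42.6 %, inner medulla
#' 76.4 %). Default short-component T2 values (38 / 35 / 30 ms) are chosen
#' inside the fitting bounds 10--40 ms; the in vivo per-layer
#' mono-exponential T2 values are composites of both compartments and are
#' deliberately not used as generator inputs.
#'
#' @param gridSize image size c(rows, cols)
#' @param tvfPercent named per-layer true TVF (%)
#' @param t2ShortMs named per-layer short-component T2 (ms)
#' @param t2LongMs global tubular-fluid T2 (ms)
#' @param t1ShortMs,t1LongMs T1 values for the EPG simulation (ms)
#' @param m0 magnetization scale
#' @param snr per-voxel signal-to-noise ratio; `Inf` for noiseless
#' @param protocol a [MESEProtocol-class]
#' @param rngSeed integer seed
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(gridSize = c(96L, 96L),
                        tvfPercent = c(cortex = 29.8, outer_medulla = 42.6,
                                       inner_medulla = 76.4),
                        t2ShortMs = c(cortex = 38, outer_medulla = 35,
                                      inner_medulla = 30),
                        t2LongMs = 150, t1ShortMs = 1500, t1LongMs = 2500,
                        m0 = 1000, snr = 100,
                        protocol = protocolPreset("short_te"),
                        rngSeed = 20260101L) {
  new("PhantomSpec", gridSize = as.integer(gridSize),
      tvfPercent = tvfPercent, t2ShortMs = t2ShortMs,
      t2LongMs = as.numeric(t2LongMs), t1ShortMs = as.numeric(t1ShortMs),
      t1LongMs = as.numeric(t1LongMs), m0 = as.numeric(m0),
      snr = as.numeric(snr), protocol = protocol,
      rngSeed = as.integer(rngSeed))
}

# Nested elliptical layer label matrix: 1 cortex, 2 outer medulla,
# 3 inner medulla, 0 background. Layers are disjoint by construction.
.layerLabelMatrix <- function(gridSize) {
  nr <- gridSize[1]; nc <- gridSize[2]
  u <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
  v <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
  U <- matrix(u, nr, nc)
  V <- matrix(v, nr, nc, byrow = TRUE)
  inside <- function(a, b) (U / a)^2 + (V / b)^2 <= 1
  outer <- inside(0.85, 0.62)
  om <- inside(0.60, 0.44)
  im <- inside(0.34, 0.25)
  lab <- matrix(0L, nr, nc)
  lab[outer & !om] <- 1L
  lab[om & !im] <- 2L
  lab[im] <- 3L
  lab
}

#' Generate a layered kidney phantom image
#'
#' Every voxel's echo train is composed from its layer's two-compartment
#' parameters through the EPG simulator, then corrupted with per-voxel
#' Gaussian noise at the specified SNR. The true TVF and short-T2 maps are
#' returned for scoring, together with the layer label map. Deterministic
#' given the spec's seed.
#'
#' @param spec a [PhantomSpec-class]
#' @return list with elements `image` ([MultiEchoImage-class]), `labels`
#'   ([ROILabels-class]), `truthTvf` and `truthT2Short`
#'   ([ParametricMap-class])
#' @examples
#' ph <- generateLayeredImage(phantomSpec(gridSize = c(32L, 32L), snr = Inf))
#' roiMedian(ph$truthTvf, ph$labels)
#' @export
generateLayeredImage <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  lab <- .layerLabelMatrix(spec@gridSize)
  if (!all(1:3 %in% lab)) stop("degenerate layer geometry: empty layer")
  nr <- spec@gridSize[1]; nc <- spec@gridSize[2]
  ne <- spec@protocol@nEchoes
  eLong <- epgEchoAmplitudes(spec@t2LongMs, spec@t1LongMs, spec@protocol)
  arr <- array(0, c(nr, nc, ne))
  truthTvf <- matrix(0, nr, nc)
  truthT2s <- matrix(0, nr, nc)
  withr::with_seed(spec@rngSeed, {
    for (l in 1:3) {
      f <- spec@tvfPercent[l] / 100
      eShort <- epgEchoAmplitudes(spec@t2ShortMs[l], spec@t1ShortMs,
                                  spec@protocol)
      s <- spec@m0 * (f * eLong + (1 - f) * eShort)
      vox <- which(lab == l)
      sigma <- if (is.infinite(spec@snr)) 0 else mean(s) / spec@snr
      for (k in seq_len(ne)) {
        plane <- arr[, , k]
        plane[vox] <- s[k] +
          if (sigma > 0) rnorm(length(vox), 0, sigma) else 0
        arr[, , k] <- plane
      }
      truthTvf[vox] <- spec@tvfPercent[l]
      truthT2s[vox] <- spec@t2ShortMs[l]
    }
  })
  inKidney <- lab > 0L
  list(image = multiEchoImage(arr, spec@protocol, mask = inKidney),
       labels = roiLabels(lab),
       truthTvf = .newMap(truthTvf, inKidney, "percent"),
       truthT2Short = .newMap(truthT2s, inKidney, "ms"))
}

#' Generate a series of two-compartment mixture signals
#'
#' Emulates tube-phantom mixing: each signal is
#' `f * long-decay + (1 - f) * short-decay` (plus noise), so the ground
#' truth TVF of signal i is `100 * fractions[i]`.
#'
#' @param fractions vector of mixing fractions between 0 and 1
#' @param t2PairMs c(long, short) T2 values (ms)
#' @param t1PairMs c(long, short) T1 values (ms)
#' @param protocol a [MESEProtocol-class]
#' @param snr signal-to-noise ratio; `Inf` for noiseless
#' @param m0 magnetization scale
#' @param rngSeed integer seed
#' @return list with `signals` (list of [DecaySignal-class]) and
#'   `tvfTruthPercent`
#' @export
generateMixtureSeries <- function(fractions, t2PairMs = c(150, 30),
                                  t1PairMs = c(2500, 1500),
                                  protocol = protocolPreset("short_te"),
                                  snr = 100, m0 = 1,
                                  rngSeed = 20260101L) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  eLong <- epgEchoAmplitudes(t2PairMs[1], t1PairMs[1], protocol)
  eShort <- epgEchoAmplitudes(t2PairMs[2], t1PairMs[2], protocol)
  te <- echoTimes(protocol)
  withr::with_seed(as.integer(rngSeed), {
    signals <- lapply(fractions, function(f) {
      addGaussianNoise(decaySignal(te, m0 * (f * eLong + (1 - f) * eShort)),
                       snr)
    })
  })
  list(signals = signals, tvfTruthPercent = 100 * fractions)
}

#' Specify a per-layer intervention profile
#'
#' Multiplicative TVF effect trajectories across the time points of a
#' synthetic intervention experiment. By default the series has four
#' baseline points, a first interval of four points and a second interval
#' of three points; the multipliers are 1 at baseline and take the
#' per-layer interval effects afterwards.
#'
#' @param interval1Effect named per-layer multipliers during the first
#'   interval (cortex, outer_medulla, inner_medulla)
#' @param interval2Effect per-layer multipliers during the second interval;
#'   defaults to `interval1Effect`
#' @param nBaseline,nInterval1,nInterval2 number of time points per segment
#' @return an [InterventionProfile-class]
#' @export
interventionProfile <- function(interval1Effect = c(cortex = 1.311,
                                                    outer_medulla = 1.307,
                                                    inner_medulla = 1.088),
                                interval2Effect = interval1Effect,
                                nBaseline = 4L, nInterval1 = 4L,
                                nInterval2 = 3L) {
  mult <- cbind(matrix(1, 3, nBaseline),
                matrix(rep(interval1Effect, nInterval1), 3, nInterval1),
                matrix(rep(interval2Effect, nInterval2), 3, nInterval2))
  rownames(mult) <- names(renalLayers())
  new("InterventionProfile", multipliers = mult,
      baselineIdx = seq_len(nBaseline),
      interval1Idx = nBaseline + seq_len(nInterval1),
      interval2Idx = nBaseline + nInterval1 + seq_len(nInterval2))
}

#' Generate an intervention time series of phantom images
#'
#' At each time point the layer TVFs of the spec are scaled by the
#' profile's multipliers and a fresh phantom image is generated with an
#' independent noise realization (per-time-point seeds are derived from the
#' spec's master seed).
#'
#' @param spec a [PhantomSpec-class]
#' @param profile an [InterventionProfile-class]
#' @return list with `frames` (one [generateLayeredImage()] result per time
#'   point), `labels`, and the `profile`
#' @export
generateInterventionSeries <- function(spec, profile) {
  stopifnot(is(spec, "PhantomSpec"), is(profile, "InterventionProfile"))
  validObject(profile)
  nt <- ncol(profile@multipliers)
  tvfs <- spec@tvfPercent * profile@multipliers  # 3 x nt
  if (any(tvfs >= 100))
    stop("profile multipliers push a layer TVF to >= 100 %")
  seeds <- withr::with_seed(spec@rngSeed,
                            sample.int(.Machine$integer.max - 1L, nt))
  frames <- lapply(seq_len(nt), function(t) {
    st <- spec
    st@tvfPercent <- tvfs[, t]
    st@rngSeed <- seeds[t]
    generateLayeredImage(st)
  })
  list(frames = frames, labels = frames[[1]]$labels, profile = profile)
}
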