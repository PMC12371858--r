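## S4 classes for acquisition protocols, decay data, fits, spectra and images.

#' @rdname MESEProtocol-class
#' @export
setClass("AcqProtocol",
  representation("VIRTUAL",
    trMs = "numeric", teFirstMs = "numeric", deltaTeMs = "numeric",
    nEchoes = "integer"))

#' Multi-echo spin-echo (CPMG) acquisition protocol
#'
#' Echo-train timing and flip angles of a MESE acquisition. CPMG timing is
#' enforced: the first echo time must equal the inter-echo spacing.
#'
#' @slot trMs repetition time (ms)
#' @slot teFirstMs first echo time (ms)
#' @slot deltaTeMs inter-echo spacing (ms)
#' @slot nEchoes number of echoes
#' @slot refocusingFlipDeg refocusing flip angle in degrees, in (0, 180]
#' @slot excitationFlipDeg excitation flip angle in degrees (default 90)
#' @seealso [meseProtocol()], [protocolPreset()]
#' @export
setClass("MESEProtocol", contains = "AcqProtocol",
  representation(refocusingFlipDeg = "numeric", excitationFlipDeg = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nEchoes < 1L) msg <- c(msg, "nEchoes must be >= 1")
    if (any(c(object@trMs, object@teFirstMs, object@deltaTeMs) <= 0))
      msg <- c(msg, "all times must be > 0")
    if (abs(object@teFirstMs - object@deltaTeMs) > 1e-9)
      msg <- c(msg, "CPMG timing requires teFirstMs == deltaTeMs")
    if (object@refocusingFlipDeg <= 0 || object@refocusingFlipDeg > 180)
      msg <- c(msg, "refocusingFlipDeg must be in (0, 180]")
    if (object@excitationFlipDeg <= 0 || object@excitationFlipDeg > 180)
      msg <- c(msg, "excitationFlipDeg must be in (0, 180]")
    if (length(msg)) msg else TRUE
  })

#' Multi gradient-echo acquisition protocol
#'
#' Timing of an MGE (T2*-weighted) acquisition: a single low-flip excitation
#' per TR followed by gradient-echo sampling of the FID at the echo times.
#'
#' @slot trMs repetition time (ms)
#' @slot teFirstMs first echo time (ms)
#' @slot deltaTeMs inter-echo spacing (ms)
#' @slot nEchoes number of echoes (>= 2)
#' @slot excitationFlipDeg excitation flip angle in degrees
#' @seealso [mgeProtocol()], [protocolPreset()]
#' @export
setClass("MGEProtocol", contains = "AcqProtocol",
  representation(excitationFlipDeg = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nEchoes < 2L) msg <- c(msg, "nEchoes must be >= 2")
    if (any(c(object@trMs, object@teFirstMs, object@deltaTeMs) <= 0))
      msg <- c(msg, "all times must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Multi-compartment voxel composition
#'
#' A set of water compartments (per-compartment T2, T1 and nonnegative
#' weight) plus an overall magnetization scale, from which echo-train signals
#' are composed.
#'
#' @slot m0 overall magnetization scale (arbitrary units)
#' @slot t2Ms per-compartment transverse relaxation times (ms)
#' @slot t1Ms per-compartment longitudinal relaxation times (ms)
#' @slot weight per-compartment nonnegative weights
#' @seealso [compartmentSet()], [composeSignal()]
#' @export
setClass("CompartmentSet",
  representation(m0 = "numeric", t2Ms = "numeric", t1Ms = "numeric",
                 weight = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@t2Ms)
    if (n < 1L) msg <- c(msg, "at least one compartment is required")
    if (length(object@t1Ms) != n || length(object@weight) != n)
      msg <- c(msg, "t2Ms, t1Ms and weight must have equal length")
    if (any(object@t2Ms <= 0) || any(object@t1Ms <= 0))
      msg <- c(msg, "relaxation times must be > 0")
    if (any(object@weight < 0)) msg <- c(msg, "weights must be >= 0")
    if (length(object@m0) != 1L || object@m0 < 0)
      msg <- c(msg, "m0 must be a single nonnegative number")
    if (length(msg)) msg else TRUE
  })

#' Single-voxel (or ROI) decay signal
#'
#' Echo times and signal amplitudes for one decay curve.
#'
#' @slot teMs strictly increasing echo times (ms)
#' @slot amplitude signal amplitudes (arbitrary units), same length as teMs
#' @seealso [decaySignal()]
#' @export
setClass("DecaySignal",
  representation(teMs = "numeric", amplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@teMs) != length(object@amplitude))
      msg <- c(msg, "teMs and amplitude must have equal length")
    if (length(object@teMs) && any(diff(object@teMs) <= 0))
      msg <- c(msg, "teMs must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Constraints of the bi-exponential TVF fit
#'
#' @slot t2LongFixedMs fixed long-component T2 (ms), tubular fluid; default 150
#' @slot t2ShortBoundsMs bounds for the short-component T2 (ms); default
#'   c(10, 40), the parenchyma/blood range
#' @seealso [fitConstraints()], [fitBiExpFixedLong()]
#' @export
setClass("FitConstraints",
  representation(t2LongFixedMs = "numeric", t2ShortBoundsMs = "numeric"),
  validity = function(object) {
    msg <- character()
    b <- object@t2ShortBoundsMs
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2])
      msg <- c(msg, "t2ShortBoundsMs must be ordered positive bounds")
    if (length(object@t2LongFixedMs) != 1L ||
        object@t2LongFixedMs <= b[2])
      msg <- c(msg, "t2LongFixedMs must exceed the upper short-T2 bound")
    if (length(msg)) msg else TRUE
  })

#' Mono-exponential fit result
#'
#' @slot s0 amplitude extrapolated to t = 0
#' @slot t2Ms fitted decay constant (T2 or T2* depending on protocol)
#' @slot residualNorm root sum of squared residuals
#' @slot valid whether the fit is usable
#' @export
setClass("MonoExpFit",
  representation(s0 = "numeric", t2Ms = "numeric", residualNorm = "numeric",
                 valid = "logical"))

#' Constrained bi-exponential fit result
#'
#' The decay is modeled as `a1 * exp(-t/t2Long) + a2 * exp(-t/t2Short)` with
#' `t2Long` clamped to a fixed value and `t2Short` bounded. The tubular
#' volume fraction is `100 * a1 / (a1 + a2)`.
#'
#' @slot a1 weight of the long (tubular fluid) component
#' @slot a2 weight of the short (parenchyma/blood) component
#' @slot t2ShortMs fitted short T2 (ms), within bounds
#' @slot t2LongMs the fixed long T2 (ms)
#' @slot tvfPercent tubular volume fraction (%)
#' @slot residualNorm root sum of squared residuals
#' @slot valid whether the fit is usable
#' @export
setClass("BiExpFit",
  representation(a1 = "numeric", a2 = "numeric", t2ShortMs = "numeric",
                 t2LongMs = "numeric", tvfPercent = "numeric",
                 residualNorm = "numeric", valid = "logical"))

#' Nonnegative T2 spectrum
#'
#' Amplitude distribution over a log-spaced T2 grid obtained by unregularized
#' nonnegative least squares ("free fit").
#'
#' @slot t2GridMs strictly increasing (log-spaced) T2 grid (ms)
#' @slot amplitude nonnegative amplitudes, same length as the grid
#' @slot residualNorm root sum of squared residuals of the reconstruction
#' @seealso [nnlsSpectrum()], [findPeaks()]
#' @export
setClass("T2Spectrum",
  representation(t2GridMs = "numeric", amplitude = "numeric",
                 residualNorm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@t2GridMs) != length(object@amplitude))
      msg <- c(msg, "grid and amplitude must have equal length")
    if (any(diff(object@t2GridMs) <= 0))
      msg <- c(msg, "t2GridMs must be strictly increasing")
    if (any(object@amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Configuration of the long-T2 fixation error study
#'
#' Defaults reproduce the study conditions: 13-echo CPMG with
#' TE1 = dTE = 6.4 ms, refocusing 170 degrees, short compartment T2 = 30 ms,
#' long-T2 truths 100/150/200 ms all fitted with the long T2 fixed at 150 ms,
#' SNR 100, nine fits averaged per trial, 1000 trials, TVF levels
#' 15--80 % in 5 % steps (the 15 % level is the predecessor needed for the
#' relative change reported at 20 %).
#'
#' @slot tvfLevelsPercent strictly increasing true TVF levels in (0, 100)
#' @slot t2LongTrueMs set of simulated long-T2 truths (ms)
#' @slot t2ShortTrueMs simulated short-compartment T2 (ms)
#' @slot t1ShortMs,t1LongMs longitudinal relaxation times used by the EPG
#'   simulation (ms)
#' @slot constraints [FitConstraints-class] used for fitting
#' @slot snr signal-to-noise ratio, mean(signal)/sigma; `Inf` for noiseless
#' @slot nAvg fits averaged per trial
#' @slot nTrials number of Monte Carlo trials
#' @slot m0 magnetization scale of the simulated signals
#' @slot protocol [MESEProtocol-class] of the simulated acquisition
#' @slot rngSeed integer seed making the study reproducible
#' @seealso [simulationConfig()], [runTable2()]
#' @export
setClass("SimulationConfig",
  representation(tvfLevelsPercent = "numeric", t2LongTrueMs = "numeric",
                 t2ShortTrueMs = "numeric", t1ShortMs = "numeric",
                 t1LongMs = "numeric", constraints = "FitConstraints",
                 snr = "numeric", nAvg = "integer", nTrials = "integer",
                 m0 = "numeric", protocol = "MESEProtocol",
                 rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    lv <- object@tvfLevelsPercent
    if (!length(lv) || any(lv <= 0) || any(lv >= 100) ||
        (length(lv) > 1 && any(diff(lv) <= 0)))
      msg <- c(msg, "tvfLevelsPercent must be strictly increasing in (0, 100)")
    if (object@nAvg < 1L) msg <- c(msg, "nAvg must be >= 1")
    if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
    if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
    if (any(object@t2LongTrueMs <= 0) || object@t2ShortTrueMs <= 0)
      msg <- c(msg, "relaxation times must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Result of the long-T2 fixation error study
#'
#' One record per (simulated long T2, TVF level): the mean and SD across
#' trials of the trial-averaged fitted TVF, the mean fitted relative change
#' between consecutive levels, and the mean absolute error of that relative
#' change against ground truth.
#'
#' @slot table data.frame with columns `t2_long_true_ms`, `tvf_true_percent`,
#'   `rel_change_true_percent`, `tvf_mean_percent`, `tvf_sd_percent`,
#'   `rel_change_mean_percent`, `rel_change_mae_percent`
#' @slot config the [SimulationConfig-class] that produced it
#' @seealso [runTable2()]
#' @export
setClass("SimulationResult",
  representation(table = "data.frame", config = "SimulationConfig"))

#' Multi-echo image stack
#'
#' @slot data numeric array indexed (row, col, echo)
#' @slot protocol the acquisition protocol; its echo count must match the
#'   third dimension
#' @slot mask logical matrix of voxels to analyze
#' @export
setClass("MultiEchoImage",
  representation(data = "array", protocol = "AcqProtocol", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be a (row, col, echo) array")
    else {
      if (d[3] != object@protocol@nEchoes)
        msg <- c(msg, sprintf("echo dimension (%d) != protocol nEchoes (%d)",
                              d[3], object@protocol@nEchoes))
      if (!identical(dim(object@mask), d[1:2]))
        msg <- c(msg, "mask shape must match the image plane")
    }
    if (length(msg)) msg else TRUE
  })

#' Parametric map
#'
#' @slot values numeric matrix (ms for T2/T2*/T2', percent for TVF)
#' @slot valid logical matrix marking usable voxels
#' @slot units units label ("ms" or "percent")
#' @export
setClass("ParametricMap",
  representation(values = "matrix", valid = "matrix", units = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@valid)))
      msg <- c(msg, "values and valid must have identical shape")
    if (any(!is.finite(object@values[object@valid])))
      msg <- c(msg, "values must be finite where valid")
    if (length(msg)) msg else TRUE
  })

#' Renal layer label map
#'
#' Integer labels 0 = background, 1 = cortex, 2 = outer medulla,
#' 3 = inner medulla.
#'
#' @slot labels integer matrix of layer labels
#' @export
setClass("ROILabels",
  representation(labels = "matrix"),
  validity = function(object) {
    if (!all(object@labels %in% 0:3))
      "labels must be in {0 background, 1 cortex, 2 outer_medulla, 3 inner_medulla}"
    else TRUE
  })

#' Per-layer time course of a mapped quantity
#'
#' @slot values matrix (layer x time point) of per-layer medians
#' @slot layers layer names (rownames of `values`)
#' @slot baselineIdx indices of baseline time points
#' @slot interval1Idx indices of the first post-intervention interval
#' @slot interval2Idx indices of the second post-intervention interval
#' @seealso [layerTimeCourse()], [intervalSummary()]
#' @export
setClass("LayerTimeCourse",
  representation(values = "matrix", layers = "character",
                 baselineIdx = "integer", interval1Idx = "integer",
                 interval2Idx = "integer"),
  validity = function(object) {
    msg <- character()
    nt <- ncol(object@values)
    idx <- c(object@baselineIdx, object@interval1Idx, object@interval2Idx)
    if (any(idx < 1L) || any(idx > nt))
      msg <- c(msg, "interval indices must lie within the series")
    if (anyDuplicated(idx))
      msg <- c(msg, "baseline and interval index sets must be disjoint")
    if (length(object@layers) != nrow(object@values))
      msg <- c(msg, "one layer name per row is required")
    if (!length(object@baselineIdx)) msg <- c(msg, "baseline must be nonempty")
    if (length(msg)) msg else TRUE
  })

#' Digital layered kidney phantom specification
#'
#' Nested elliptical cortex / outer medulla / inner medulla layers with known
#' per-layer TVF and short-component T2, a global long (tubular fluid) T2,
#' and a noise level. Baseline TVF defaults are the in vivo layer values
#' 29.8 / 42.6 / 76.4 %.
#'
#' @slot gridSize image size, c(rows, cols)
#' @slot tvfPercent named per-layer true TVF (%) in (0, 100)
#' @slot t2ShortMs named per-layer short-component T2 (ms)
#' @slot t2LongMs global tubular-fluid T2 (ms)
#' @slot t1ShortMs,t1LongMs T1 values used by the EPG simulation (ms)
#' @slot m0 magnetization scale
#' @slot snr signal-to-noise ratio per voxel; `Inf` for noiseless
#' @slot protocol [MESEProtocol-class] of the simulated acquisition
#' @slot rngSeed integer seed
#' @seealso [phantomSpec()], [generateLayeredImage()]
#' @export
setClass("PhantomSpec",
  representation(gridSize = "integer", tvfPercent = "numeric",
                 t2ShortMs = "numeric", t2LongMs = "numeric",
                 t1ShortMs = "numeric", t1LongMs = "numeric", m0 = "numeric",
                 snr = "numeric", protocol = "MESEProtocol",
                 rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@gridSize) != 2L || any(object@gridSize < 16L))
      msg <- c(msg, "gridSize must be two dimensions of at least 16")
    if (length(object@tvfPercent) != 3L || length(object@t2ShortMs) != 3L)
      msg <- c(msg, "tvfPercent and t2ShortMs need one value per layer")
    if (any(object@tvfPercent <= 0) || any(object@tvfPercent >= 100))
      msg <- c(msg, "layer TVFs must be in (0, 100)")
    if (any(object@t2ShortMs <= 0) || object@t2LongMs <= 0)
      msg <- c(msg, "relaxation times must be > 0")
    if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Programmable intervention profile
#'
#' Per-layer multiplicative TVF effect trajectories over the time points of a
#' synthetic intervention experiment (baseline multipliers are 1).
#'
#' @slot multipliers matrix (layer x time point) of positive multipliers
#' @slot baselineIdx,interval1Idx,interval2Idx time point index sets
#' @seealso [interventionProfile()], [generateInterventionSeries()]
#' @export
setClass("InterventionProfile",
  representation(multipliers = "matrix", baselineIdx = "integer",
                 interval1Idx = "integer", interval2Idx = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@multipliers <= 0)) msg <- c(msg, "multipliers must be > 0")
    nt <- ncol(object@multipliers)
    idx <- c(object@baselineIdx, object@interval1Idx, object@interval2Idx)
    if (any(idx < 1L) || any(idx > nt) || anyDuplicated(idx))
      msg <- c(msg, "index sets must be disjoint and within the series")
    if (length(msg)) msg else TRUE
  })
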