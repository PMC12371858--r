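#' Echo times of a protocol or decay signal
#'
#' @param x a protocol ([MESEProtocol-class], [MGEProtocol-class]), a
#'   [DecaySignal-class] or a [MultiEchoImage-class]
#' @return numeric vector of echo times (ms)
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "AcqProtocol", function(x)
  x@teFirstMs + x@deltaTeMs * (seq_len(x@nEchoes) - 1L))

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "DecaySignal", function(x) x@teMs)

#' @rdname echoTimes
#' @export
setMethod("echoTimes", "MultiEchoImage", function(x) echoTimes(x@protocol))

#' Signal amplitudes of a decay signal
#' @param x a [DecaySignal-class]
#' @return numeric vector of amplitudes
#' @export
setGeneric("signalAmplitude", function(x) standardGeneric("signalAmplitude"))

#' @rdname signalAmplitude
#' @export
setMethod("signalAmplitude", "DecaySignal", function(x) x@amplitude)

#' Tubular volume fraction of a fit
#' @param x a [BiExpFit-class]
#' @return TVF in percent
#' @export
setGeneric("tvf", function(x) standardGeneric("tvf"))

#' @rdname tvf
#' @export
setMethod("tvf", "BiExpFit", function(x) x@tvfPercent)

#' Map values and validity
#' @param x a [ParametricMap-class]
#' @return `mapValues`: numeric matrix with invalid voxels set to `NA`;
#'   `mapValid`: logical matrix of usable voxels
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "ParametricMap", function(x) {
  v <- x@values
  v[!x@valid] <- NA_real_
  v
})

#' @rdname mapValues
#' @export
setGeneric("mapValid", function(x) standardGeneric("mapValid"))

#' @rdname mapValues
#' @export
setMethod("mapValid", "ParametricMap", function(x) x@valid)

#' Result table of a simulation study
#' @param x a [SimulationResult-class]
#' @param ... unused
#' @return data.frame, one row per (long-T2 truth, TVF level)
#' @export
setMethod("as.data.frame", "SimulationResult", function(x, ...) x@table)

setMethod("show", "MESEProtocol", function(object) {
  cat(sprintf(
    "MESE protocol: %d echoes, TE1 = dTE = %g ms, TR = %g ms, refocusing %g deg\n",
    object@nEchoes, object@deltaTeMs, object@trMs, object@refocusingFlipDeg))
})

setMethod("show", "MGEProtocol", function(object) {
  cat(sprintf(
    "MGE protocol: %d echoes, TE1 = %g ms, dTE = %g ms, TR = %g ms, flip %g deg\n",
    object@nEchoes, object@teFirstMs, object@deltaTeMs, object@trMs,
    object@excitationFlipDeg))
})

setMethod("show", "DecaySignal", function(object) {
  n <- length(object@teMs)
  cat(sprintf("DecaySignal: %d echoes, TE %g..%g ms\n", n,
              if (n) min(object@teMs) else NA, if (n) max(object@teMs) else NA))
})

setMethod("show", "BiExpFit", function(object) {
  cat(sprintf(
    "BiExpFit: TVF = %.2f %%, T2short = %.2f ms (T2long fixed %g ms), %s\n",
    object@tvfPercent, object@t2ShortMs, object@t2LongMs,
    if (object@valid) "valid" else "INVALID"))
})

setMethod("show", "MonoExpFit", function(object) {
  cat(sprintf("MonoExpFit: T2 = %.2f ms, s0 = %.3g, %s\n", object@t2Ms,
              object@s0, if (object@valid) "valid" else "INVALID"))
})

setMethod("show", "T2Spectrum", function(object) {
  cat(sprintf("T2Spectrum: %d grid points %g..%g ms, %d nonzero\n",
              length(object@t2GridMs), min(object@t2GridMs),
              max(object@t2GridMs), sum(object@amplitude > 0)))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("Long-T2 fixation error study: %d scenario(s) x %d level(s), %d trials\n",
              length(object@config@t2LongTrueMs),
              length(object@config@tvfLevelsPercent), object@config@nTrials))
  print(object@table, digits = 4)
})

setMethod("show", "MultiEchoImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiEchoImage: %d x %d voxels, %d echoes (%s), %d in mask\n",
              d[1], d[2], d[3], class(object@protocol), sum(object@mask)))
})

setMethod("show", "ParametricMap", function(object) {
  cat(sprintf("ParametricMap (%s): %d x %d, %d valid voxels\n", object@units,
              nrow(object@values), ncol(object@values), sum(object@valid)))
})
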