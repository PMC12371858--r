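#' Construct a multi-echo spin-echo (CPMG) protocol
#'
#' @param trMs repetition time (ms)
#' @param teFirstMs first echo time (ms); CPMG timing requires it to equal
#'   `deltaTeMs`
#' @param deltaTeMs inter-echo spacing (ms)
#' @param nEchoes number of echoes
#' @param refocusingFlipDeg refocusing flip angle (degrees), in (0, 180]
#' @param excitationFlipDeg excitation flip angle (degrees)
#' @return a [MESEProtocol-class]
#' @examples
#' meseProtocol(trMs = 500, teFirstMs = 6.4, deltaTeMs = 6.4, nEchoes = 13,
#'              refocusingFlipDeg = 170)
#' @export
meseProtocol <- function(trMs, teFirstMs, deltaTeMs, nEchoes,
                         refocusingFlipDeg = 180, excitationFlipDeg = 90) {
  new("MESEProtocol", trMs = as.numeric(trMs), teFirstMs = as.numeric(teFirstMs),
      deltaTeMs = as.numeric(deltaTeMs), nEchoes = as.integer(nEchoes),
      refocusingFlipDeg = as.numeric(refocusingFlipDeg),
      excitationFlipDeg = as.numeric(excitationFlipDeg))
}

#' Construct a multi gradient-echo protocol
#'
#' @param trMs repetition time (ms)
#' @param teFirstMs first echo time (ms)
#' @param deltaTeMs inter-echo spacing (ms)
#' @param nEchoes number of echoes (>= 2)
#' @param excitationFlipDeg excitation flip angle (degrees)
#' @return an [MGEProtocol-class]
#' @export
mgeProtocol <- function(trMs, teFirstMs, deltaTeMs, nEchoes,
                        excitationFlipDeg = 16) {
  new("MGEProtocol", trMs = as.numeric(trMs), teFirstMs = as.numeric(teFirstMs),
      deltaTeMs = as.numeric(deltaTeMs), nEchoes = as.integer(nEchoes),
      excitationFlipDeg = as.numeric(excitationFlipDeg))
}

#' Named acquisition protocol presets
#'
#' Three presets mirror the acquisition parameters of the study protocols:
#' \describe{
#'   \item{`"long_te"`}{42-echo CPMG, TE1 = dTE = 6.96 ms, TR = 2000 ms,
#'     nominal 180 deg refocusing; used for T2 spectrum analysis.}
#'   \item{`"short_te"`}{13-echo CPMG, TE1 = dTE = 6.4 ms, TR = 500 ms;
#'     used for T2/TVF mapping. The refocusing flip defaults to 170 deg to
#'     account for imperfect refocusing pulses.}
#'   \item{`"mge"`}{10-echo gradient echo, TE1 = dTE = 2.1 ms, TR = 50 ms,
#'     16 deg excitation; used for T2* mapping.}
#' }
#'
#' @param name one of `"long_te"`, `"short_te"`, `"mge"`
#' @param refocusingFlipDeg refocusing flip angle override for the CPMG
#'   presets
#' @return a protocol object
#' @examples
#' protocolPreset("short_te")
#' @export
protocolPreset <- function(name = c("short_te", "long_te", "mge"),
                           refocusingFlipDeg = NULL) {
  name <- match.arg(name)
  switch(name,
    long_te = meseProtocol(2000, 6.96, 6.96, 42L,
                           refocusingFlipDeg %||% 180),
    short_te = meseProtocol(500, 6.4, 6.4, 13L,
                            refocusingFlipDeg %||% 170),
    mge = mgeProtocol(50, 2.1, 2.1, 10L, 16))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize a protocol as a plain list
#'
#' Used for YAML/JSON sidecar files.
#'
#' @param protocol a protocol object
#' @return `protocolToList`: a named list; `protocolFromList`: a protocol
#' @export
protocolToList <- function(protocol) {
  out <- list(type = if (is(protocol, "MESEProtocol")) "mese" else "mge",
              tr_ms = protocol@trMs, te_first_ms = protocol@teFirstMs,
              delta_te_ms = protocol@deltaTeMs, n_echoes = protocol@nEchoes,
              excitation_flip_deg = protocol@excitationFlipDeg)
  if (is(protocol, "MESEProtocol"))
    out$refocusing_flip_deg <- protocol@refocusingFlipDeg
  out
}

#' @rdname protocolToList
#' @param x a named list as produced by `protocolToList`
#' @export
protocolFromList <- function(x) {
  if (is.null(x$type)) stop("protocol list lacks a 'type' field")
  if (x$type == "mese")
    meseProtocol(x$tr_ms, x$te_first_ms, x$delta_te_ms, x$n_echoes,
                 x$refocusing_flip_deg %||% 180, x$excitation_flip_deg %||% 90)
  else if (x$type == "mge")
    mgeProtocol(x$tr_ms, x$te_first_ms, x$delta_te_ms, x$n_echoes,
                x$excitation_flip_deg %||% 16)
  else stop("unknown protocol type: ", x$type)
}

#' Construct a compartment set
#'
#' @param t2Ms per-compartment T2 (ms)
#' @param weight per-compartment nonnegative weights
#' @param t1Ms per-compartment T1 (ms); defaults to 1500 ms, the order of
#'   magnitude of renal tissue at high field
#' @param m0 overall magnetization scale
#' @return a [CompartmentSet-class]
#' @examples
#' # two-compartment kidney voxel at 50 % tubular volume fraction
#' compartmentSet(t2Ms = c(150, 30), weight = c(0.5, 0.5),
#'                t1Ms = c(2500, 1500))
#' @export
compartmentSet <- function(t2Ms, weight, t1Ms = rep(1500, length(t2Ms)),
                           m0 = 1) {
  if (!length(t2Ms)) stop("at least one compartment is required")
  new("CompartmentSet", m0 = as.numeric(m0), t2Ms = as.numeric(t2Ms),
      t1Ms = as.numeric(t1Ms), weight = as.numeric(weight))
}

#' Construct a decay signal
#'
#' @param teMs strictly increasing echo times (ms)
#' @param amplitude amplitudes of matching length
#' @return a [DecaySignal-class]
#' @export
decaySignal <- function(teMs, amplitude) {
  new("DecaySignal", teMs = as.numeric(teMs), amplitude = as.numeric(amplitude))
}

#' Construct bi-exponential fit constraints
#'
#' Defaults are the study constraints: long T2 fixed at 150 ms (tubular
#' fluid), short T2 bounded in 10--40 ms (parenchyma and blood).
#'
#' @param t2LongFixedMs fixed long-component T2 (ms)
#' @param t2ShortBoundsMs length-2 bounds for the short-component T2 (ms)
#' @return a [FitConstraints-class]
#' @export
fitConstraints <- function(t2LongFixedMs = 150, t2ShortBoundsMs = c(10, 40)) {
  new("FitConstraints", t2LongFixedMs = as.numeric(t2LongFixedMs),
      t2ShortBoundsMs = as.numeric(t2ShortBoundsMs))
}
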