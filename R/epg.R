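#' EPG echo amplitudes of a CPMG echo train
#'
#' Computes the echo-train amplitudes of a single compartment under a
#' multi-echo spin-echo protocol using the extended phase graph (EPG)
#' formalism. The recursion tracks the transverse configuration states
#' F+(k), F-(k) and the longitudinal states Z(k), so stimulated-echo
#' pathways arising from imperfect (< 180 deg) refocusing pulses are
#' included. Ideal crusher gradients are assumed (one dephasing step per
#' half inter-echo interval); diffusion is not modeled. With a perfect
#' 180 deg refocusing pulse the recursion reduces exactly to
#' `exp(-TE_k / t2Ms)`.
#'
#' The CPMG phase convention is used: excitation about y, refocusing about
#' x. T1 enters through the longitudinal storage of stimulated-echo
#' pathways; longitudinal recovery towards equilibrium within the echo train
#' is included.
#'
#' @param t2Ms transverse relaxation time (ms), > 0
#' @param t1Ms longitudinal relaxation time (ms), > 0
#' @param protocol a [MESEProtocol-class]
#' @return numeric vector of `nEchoes` unit-scale echo amplitudes between 0 and 1;
#'   echo k is evaluated at `TE_k = teFirst + (k - 1) * deltaTe`
#' @seealso [blochEchoAmplitudes()] for the brute-force isochromat oracle,
#'   [composeSignal()] for multi-compartment signals
#' @examples
#' p <- protocolPreset("short_te", refocusingFlipDeg = 180)
#' amp <- epgEchoAmplitudes(30, 1500, p)
#' all.equal(amp, exp(-echoTimes(p) / 30))
#' @export
epgEchoAmplitudes <- function(t2Ms, t1Ms, protocol) {
  .checkRelaxation(t2Ms, t1Ms)
  if (!is(protocol, "MESEProtocol"))
    stop("epgEchoAmplitudes requires a MESEProtocol")
  n <- protocol@nEchoes
  alpha <- protocol@refocusingFlipDeg * pi / 180
  exc <- protocol@excitationFlipDeg * pi / 180
  tau <- protocol@deltaTeMs / 2
  E1 <- exp(-tau / t1Ms)
  E2 <- exp(-tau / t2Ms)
  nStates <- n + 1L

  # configuration state matrix: rows F+(k), F-(k), Z(k), k = 0 .. n
  Q <- matrix(0 + 0i, 3L, nStates)
  Q[3L, 1L] <- 1 + 0i

  rf <- function(Q, a, phi) {
    T <- rbind(
      c(cos(a / 2)^2, exp(2i * phi) * sin(a / 2)^2, -1i * exp(1i * phi) * sin(a)),
      c(exp(-2i * phi) * sin(a / 2)^2, cos(a / 2)^2, 1i * exp(-1i * phi) * sin(a)),
      c(-0.5i * exp(-1i * phi) * sin(a), 0.5i * exp(1i * phi) * sin(a), cos(a)))
    T %*% Q
  }
  relax <- function(Q) {
    Q[1:2, ] <- Q[1:2, ] * E2
    Q[3, ] <- Q[3, ] * E1
    Q[3, 1] <- Q[3, 1] + (1 - E1)
    Q
  }
  dephase <- function(Q) {
    k <- ncol(Q)
    Q[1, ] <- c(0i, Q[1, -k])
    Q[2, ] <- c(Q[2, -1], 0i)
    Q[1, 1] <- Conj(Q[2, 1])
    Q
  }

  Q <- rf(Q, exc, pi / 2)
  amp <- numeric(n)
  for (k in seq_len(n)) {
    Q <- dephase(relax(Q))
    Q <- rf(Q, alpha, 0)
    Q <- dephase(relax(Q))
    amp[k] <- Mod(Q[1, 1])
  }
  amp
}

#' Isochromat Bloch-simulation echo amplitudes
#'
#' Brute-force reference for [epgEchoAmplitudes()]: the voxel is modeled as
#' `nSpins` isochromats whose crusher-induced dephasing per half inter-echo
#' interval is spread uniformly over one full cycle. Each isochromat evolves
#' under exact rotations and T1/T2 relaxation; the echo amplitude is the
#' magnitude of the complex mean transverse magnetization. This
#' implementation shares no code with the EPG recursion and serves as its
#' independent oracle.
#'
#' @inheritParams epgEchoAmplitudes
#' @param nSpins number of isochromats (>= 1000 recommended)
#' @return numeric vector of `nEchoes` echo amplitudes
#' @export
blochEchoAmplitudes <- function(t2Ms, t1Ms, protocol, nSpins = 10000L) {
  .checkRelaxation(t2Ms, t1Ms)
  if (!is(protocol, "MESEProtocol"))
    stop("blochEchoAmplitudes requires a MESEProtocol")
  n <- protocol@nEchoes
  a <- protocol@refocusingFlipDeg * pi / 180
  exc <- protocol@excitationFlipDeg * pi / 180
  tau <- protocol@deltaTeMs / 2
  E1 <- exp(-tau / t1Ms)
  E2 <- exp(-tau / t2Ms)

  psi <- 2 * pi * (seq_len(nSpins) - 0.5) / nSpins
  cp <- cos(psi); sp <- sin(psi)
  Mx <- numeric(nSpins); My <- numeric(nSpins); Mz <- rep(1, nSpins)

  # excitation about y: z -> x
  tmp <- Mx * cos(exc) + Mz * sin(exc)
  Mz <- -Mx * sin(exc) + Mz * cos(exc)
  Mx <- tmp

  ca <- cos(a); sa <- sin(a)
  amp <- numeric(n)
  for (k in seq_len(n)) {
    for (h in 1:2) {
      Mx <- Mx * E2; My <- My * E2; Mz <- Mz * E1 + (1 - E1)
      tx <- Mx * cp - My * sp
      My <- Mx * sp + My * cp
      Mx <- tx
      if (h == 1L) { # refocusing about x
        ty <- My * ca - Mz * sa
        Mz <- My * sa + Mz * ca
        My <- ty
      }
    }
    amp[k] <- Mod(complex(real = mean(Mx), imaginary = mean(My)))
  }
  amp
}

#' Compose a multi-compartment echo-train signal
#'
#' The noiseless signal is the weight-linear combination of the single
#' compartment echo trains: `M0 * sum_j D_j * EPG(T2_j, T1_j)` for a CPMG
#' protocol, or mono-exponential FID sampling
#' `M0 * sum_j D_j * exp(-TE_k / T2_j)` for a gradient-echo protocol (one RF
#' pulse per TR, so no refocusing dynamics; T2 is then interpreted as T2*).
#'
#' @param compartments a [CompartmentSet-class]
#' @param protocol a [MESEProtocol-class] or [MGEProtocol-class]
#' @return a noiseless [DecaySignal-class]
#' @examples
#' cs <- compartmentSet(c(150, 30), c(0.5, 0.5), c(2500, 1500))
#' composeSignal(cs, protocolPreset("short_te"))
#' @export
composeSignal <- function(compartments, protocol) {
  stopifnot(is(compartments, "CompartmentSet"))
  validObject(compartments)
  te <- echoTimes(protocol)
  amp <- numeric(length(te))
  for (j in seq_along(compartments@t2Ms)) {
    base <- if (is(protocol, "MESEProtocol"))
      epgEchoAmplitudes(compartments@t2Ms[j], compartments@t1Ms[j], protocol)
    else
      exp(-te / compartments@t2Ms[j])
    amp <- amp + compartments@weight[j] * base
  }
  decaySignal(te, compartments@m0 * amp)
}

#' Add white Gaussian noise to a decay signal
#'
#' Adds i.i.d. zero-mean real Gaussian noise with standard deviation
#' `sigma = mean(amplitude) / snr`, the SNR convention of magnitude images
#' (SNR = mean signal over noise SD). No magnitude operation is applied, so
#' the noise is additive Gaussian, not Rician.
#'
#' @param signal a noiseless [DecaySignal-class]
#' @param snr signal-to-noise ratio, > 0; `Inf` returns the signal unchanged
#' @param rngSeed optional integer seed; when given, the draw is
#'   reproducible and the caller's RNG state is left untouched
#' @return a noisy [DecaySignal-class]
#' @export
addGaussianNoise <- function(signal, snr, rngSeed = NULL) {
  stopifnot(is(signal, "DecaySignal"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("snr must be a single positive number")
  if (is.infinite(snr)) return(signal)
  sigma <- mean(signal@amplitude) / snr
  draw <- function() rnorm(length(signal@amplitude), 0, sigma)
  eps <- if (is.null(rngSeed)) draw() else withr::with_seed(as.integer(rngSeed), draw())
  decaySignal(signal@teMs, signal@amplitude + eps)
}

.checkRelaxation <- function(t2Ms, t1Ms) {
  if (!is.numeric(t2Ms) || length(t2Ms) != 1L || !is.finite(t2Ms) || t2Ms <= 0)
    stop("t2Ms must be a single finite number > 0")
  if (!is.numeric(t1Ms) || length(t1Ms) != 1L || !is.finite(t1Ms) || t1Ms <= 0)
    stop("t1Ms must be a single finite number > 0")
  invisible(TRUE)
}
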