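#' Log-spaced T2 grid for spectrum analysis
#'
#' Default: 120 log-spaced points from 5 to 500 ms, covering both the
#' parenchyma/blood range (10--40 ms) and the tubular-fluid range
#' (80--220 ms) with margin.
#'
#' @param n number of grid points
#' @param fromMs,toMs grid limits (ms)
#' @return strictly increasing numeric vector
#' @export
t2LogGrid <- function(n = 120L, fromMs = 5, toMs = 500) {
  stopifnot(n >= 2L, fromMs > 0, toMs > fromMs)
  exp(seq(log(fromMs), log(toMs), length.out = n))
}

#' Exponential decay basis matrix
#'
#' Entry (k, m) is `exp(-TE_k / T2_m)`.
#'
#' @param teMs echo times (ms)
#' @param t2GridMs T2 grid (ms)
#' @return matrix of dimension `length(teMs) x length(t2GridMs)`
#' @export
buildDecayBasis <- function(teMs, t2GridMs) {
  if (!length(teMs) || !length(t2GridMs)) stop("grids must be nonempty")
  if (any(teMs <= 0) || any(t2GridMs <= 0)) stop("times must be > 0")
  exp(-teMs %o% (1 / t2GridMs))
}

#' Free NNLS T2 spectrum
#'
#' Estimates a nonnegative amplitude distribution over a log-spaced T2 grid
#' by nonnegative least squares ("free fit": no regularization, no
#' constraint on the number of peaks). Long echo trains (the 42-echo
#' long-TE protocol) are recommended for resolving the two renal water
#' compartments.
#'
#' @param signal a [DecaySignal-class] with at least 2 echoes
#' @param t2GridMs T2 grid (ms); default [t2LogGrid()]
#' @param lambda optional Tikhonov weight for a regularized variant
#'   (rows `sqrt(lambda) * I` appended to the basis); 0 (default) is the
#'   free fit
#' @return a [T2Spectrum-class]
#' @examples
#' p <- protocolPreset("long_te")
#' te <- echoTimes(p)
#' s <- decaySignal(te, 0.4 * exp(-te / 150) + 0.6 * exp(-te / 30))
#' sp <- nnlsSpectrum(s)
#' findPeaks(sp)
#' @export
nnlsSpectrum <- function(signal, t2GridMs = t2LogGrid(), lambda = 0) {
  stopifnot(is(signal, "DecaySignal"))
  y <- signal@amplitude
  if (length(y) < 2L) stop("spectrum analysis needs >= 2 echoes")
  if (!all(is.finite(y))) stop("signal must be finite")
  A <- buildDecayBasis(signal@teMs, t2GridMs)
  m <- length(t2GridMs)
  if (all(y == 0)) {
    x <- numeric(m)
  } else {
    Afit <- A
    yfit <- y
    if (lambda > 0) {
      Afit <- rbind(A, sqrt(lambda) * diag(m))
      yfit <- c(y, numeric(m))
    }
    x <- pracma::lsqnonneg(Afit, yfit)$x
  }
  new("T2Spectrum", t2GridMs = t2GridMs, amplitude = pmax(x, 0),
      residualNorm = sqrt(sum((drop(A %*% x) - y)^2)))
}

#' Segment a T2 spectrum into peaks
#'
#' Peaks are maximal contiguous runs of strictly positive amplitude. Runs
#' whose area fraction (sum of amplitudes over total) is below
#' `minAreaFraction` are discarded as noise spikes; the remaining area
#' fractions are renormalized to sum to 1.
#'
#' @param spectrum a [T2Spectrum-class]
#' @param minAreaFraction minimum retained area fraction (default 0.02)
#' @return data.frame with one row per retained peak: `t2_low_ms`,
#'   `t2_apex_ms`, `t2_high_ms` (support bounds and location of the
#'   maximum) and `area_fraction`; zero rows for an all-zero spectrum
#' @export
findPeaks <- function(spectrum, minAreaFraction = 0.02) {
  stopifnot(is(spectrum, "T2Spectrum"))
  amp <- spectrum@amplitude
  grid <- spectrum@t2GridMs
  empty <- data.frame(t2_low_ms = numeric(), t2_apex_ms = numeric(),
                      t2_high_ms = numeric(), area_fraction = numeric())
  total <- sum(amp)
  if (total <= 0) return(empty)
  r <- rle(amp > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- do.call(rbind, lapply(runs, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(t2_low_ms = grid[idx[1]],
               t2_apex_ms = grid[idx[which.max(amp[idx])]],
               t2_high_ms = grid[idx[length(idx)]],
               area_fraction = sum(amp[idx]) / total)
  }))
  out <- out[out$area_fraction >= minAreaFraction, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$area_fraction <- out$area_fraction / sum(out$area_fraction)
  rownames(out) <- NULL
  out
}
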