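## Relaxometry model fits.
##
## Both fits use variable projection: for any candidate decay constant the
## amplitudes have a closed-form (nonnegative) least-squares solution, so the
## nonlinear search is over a single bounded parameter. A coarse grid
## localizes the global minimum and a golden-section refinement polishes it.
## The search is deterministic, needs no starting values, cannot fail to
## converge, and vectorizes over many signals at once (columns of Y).

# Amplitudes and residual sum of squares of the bi-exponential model for a
# candidate short T2 (scalar, or one value per signal). Y is nEchoes x M.
.biexpProfile <- function(t2s, Y, te, b1, s11, r1, yy) {
  M <- ncol(Y)
  if (length(t2s) == 1L) {
    b2 <- exp(-te / t2s)
    s12 <- rep(sum(b1 * b2), M)
    s22 <- rep(sum(b2 * b2), M)
    r2 <- drop(crossprod(b2, Y))
  } else {
    B2 <- exp(-te %o% (1 / t2s))
    s12 <- colSums(b1 * B2)
    s22 <- colSums(B2 * B2)
    r2 <- colSums(B2 * Y)
  }
  dt <- s11 * s22 - s12^2
  a1 <- (s22 * r1 - s12 * r2) / dt
  a2 <- (s11 * r2 - s12 * r1) / dt
  bad <- which(!(a1 >= 0 & a2 >= 0))
  if (length(bad)) {
    # unconstrained optimum infeasible: best solution lies on an axis
    a2A <- pmax(r2[bad] / s22[bad], 0)
    a1B <- pmax(r1[bad] / s11, 0)
    rssA <- yy[bad] - 2 * a2A * r2[bad] + a2A^2 * s22[bad]
    rssB <- yy[bad] - 2 * a1B * r1[bad] + a1B^2 * s11
    useA <- rssA <= rssB
    a1[bad] <- ifelse(useA, 0, a1B)
    a2[bad] <- ifelse(useA, a2A, 0)
  }
  rss <- yy - 2 * (a1 * r1 + a2 * r2) +
    a1^2 * s11 + 2 * a1 * a2 * s12 + a2^2 * s22
  list(a1 = a1, a2 = a2, rss = pmax(rss, 0))
}

# Vectorized golden-section minimization of fn(x)$rss over per-signal
# brackets [lo, hi]; returns the final profile evaluation at the midpoints.
.goldenProfile <- function(fn, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- fn(x1)$rss
  f2 <- fn(x2)$rss
  while (max(hi - lo) > tol) {
    m <- f1 > f2
    lo[m] <- x1[m]; x1[m] <- x2[m]; f1[m] <- f2[m]
    hi[!m] <- x2[!m]; x2[!m] <- x1[!m]; f2[!m] <- f1[!m]
    xn <- ifelse(m, lo + gr * (hi - lo), hi - gr * (hi - lo))
    fNew <- fn(xn)$rss
    x2[m] <- xn[m]; f2[m] <- fNew[m]
    x1[!m] <- xn[!m]; f1[!m] <- fNew[!m]
  }
  (lo + hi) / 2
}

# Batch bi-exponential fit with fixed long T2. Y: nEchoes x M matrix.
.biexpBatch <- function(Y, te, constraints = fitConstraints(),
                        gridStepMs = 1, tolMs = 1e-5) {
  M <- ncol(Y)
  bounds <- constraints@t2ShortBoundsMs
  yy <- colSums(Y * Y)
  b1 <- exp(-te / constraints@t2LongFixedMs)
  s11 <- sum(b1^2)
  r1 <- drop(crossprod(b1, Y))
  prof <- function(t2s) .biexpProfile(t2s, Y, te, b1, s11, r1, yy)

  cand <- unique(c(seq(bounds[1], bounds[2], by = gridStepMs), bounds[2]))
  bestR <- rep(Inf, M)
  bestT <- rep(cand[1], M)
  for (t in cand) {
    f <- prof(t)
    u <- f$rss < bestR
    bestR[u] <- f$rss[u]
    bestT[u] <- t
  }
  lo <- pmax(bounds[1], bestT - gridStepMs)
  hi <- pmin(bounds[2], bestT + gridStepMs)
  t2s <- .goldenProfile(prof, lo, hi, tolMs)
  f <- prof(t2s)
  tot <- f$a1 + f$a2
  valid <- is.finite(tot) & tot > 0
  tvf <- ifelse(valid, 100 * f$a1 / tot, NA_real_)
  list(a1 = f$a1, a2 = f$a2, t2ShortMs = t2s, rss = f$rss,
       tvfPercent = tvf, valid = valid)
}

# Batch mono-exponential fit; decay constant profiled on a log grid.
.monoexpBatch <- function(Y, te, t2RangeMs = c(1, 2000), nGrid = 60L,
                          tolLog = 1e-8) {
  M <- ncol(Y)
  yy <- colSums(Y * Y)
  prof <- function(logT2) {
    B <- exp(-te %o% (1 / exp(logT2)))
    if (length(logT2) == 1L) B <- matrix(B, length(te), 1L)
    s <- colSums(B * B)
    r <- colSums(B * Y)
    s0 <- pmax(r / s, 0)
    list(s0 = s0, rss = pmax(yy - 2 * s0 * r + s0^2 * s, 0))
  }
  cand <- seq(log(t2RangeMs[1]), log(t2RangeMs[2]), length.out = nGrid)
  step <- cand[2] - cand[1]
  bestR <- rep(Inf, M)
  bestT <- rep(cand[1], M)
  for (lt in cand) {
    f <- prof(rep(lt, M))
    u <- f$rss < bestR
    bestR[u] <- f$rss[u]
    bestT[u] <- lt
  }
  lo <- pmax(cand[1], bestT - step)
  hi <- pmin(cand[nGrid], bestT + step)
  logT2 <- .goldenProfile(prof, lo, hi, tolLog)
  f <- prof(logT2)
  valid <- is.finite(f$s0) & f$s0 > 0
  list(s0 = f$s0, t2Ms = exp(logT2), rss = f$rss, valid = valid)
}

#' Mono-exponential T2 (or T2*) fit
#'
#' Least-squares fit of `s0 * exp(-t / t2)` to a decay signal. The decay
#' constant is profiled over a bounded log-spaced search (the amplitude has
#' a closed-form solution for each candidate), which is deterministic and
#' free of convergence failures.
#'
#' @param signal a [DecaySignal-class] with at least 3 echoes
#' @param t2RangeMs search range for the decay constant (ms)
#' @return a [MonoExpFit-class]; an all-nonpositive signal yields an invalid
#'   fit (`NA` downstream rather than an error)
#' @examples
#' p <- protocolPreset("short_te")
#' s <- decaySignal(echoTimes(p), exp(-echoTimes(p) / 40))
#' fitMonoExp(s)
#' @export
fitMonoExp <- function(signal, t2RangeMs = c(1, 2000)) {
  stopifnot(is(signal, "DecaySignal"))
  if (length(signal@teMs) < 3L) stop("mono-exponential fit needs >= 3 echoes")
  if (!all(is.finite(signal@amplitude))) stop("signal must be finite")
  f <- .monoexpBatch(matrix(signal@amplitude, ncol = 1L), signal@teMs,
                     t2RangeMs)
  new("MonoExpFit", s0 = f$s0, t2Ms = f$t2Ms, residualNorm = sqrt(f$rss),
      valid = f$valid)
}

#' Constrained bi-exponential fit with fixed long T2
#'
#' Fits `a1 * exp(-t / t2Long) + a2 * exp(-t / t2Short)` with `t2Long`
#' clamped to the fixed tubular-fluid value, nonnegative weights, and
#' `t2Short` inside hard box bounds (fits ending on a bound are valid).
#' The tubular volume fraction is `100 * a1 / (a1 + a2)`.
#'
#' For each candidate `t2Short` the nonnegative weights solve a closed-form
#' 2x2 least-squares problem; `t2Short` itself is found by a coarse grid
#' plus golden-section refinement over the bounds. Negative or zero noisy
#' samples are used as-is by the least-squares objective.
#'
#' @param signal a [DecaySignal-class] with at least 4 echoes
#' @param constraints a [FitConstraints-class]
#' @return a [BiExpFit-class]; a signal that is nonpositive everywhere
#'   yields an invalid fit
#' @examples
#' p <- protocolPreset("short_te", refocusingFlipDeg = 180)
#' te <- echoTimes(p)
#' s <- decaySignal(te, 0.5 * exp(-te / 150) + 0.5 * exp(-te / 30))
#' fitBiExpFixedLong(s)  # recovers TVF = 50
#' @export
fitBiExpFixedLong <- function(signal, constraints = fitConstraints()) {
  stopifnot(is(signal, "DecaySignal"))
  validObject(constraints)
  if (length(signal@teMs) < 4L) stop("bi-exponential fit needs >= 4 echoes")
  if (!all(is.finite(signal@amplitude))) stop("signal must be finite")
  f <- .biexpBatch(matrix(signal@amplitude, ncol = 1L), signal@teMs,
                   constraints)
  new("BiExpFit", a1 = f$a1, a2 = f$a2, t2ShortMs = f$t2ShortMs,
      t2LongMs = constraints@t2LongFixedMs,
      tvfPercent = if (f$valid) f$tvfPercent else NA_real_,
      residualNorm = sqrt(f$rss), valid = f$valid)
}

#' Tubular volume fraction from bi-exponential weights
#'
#' The ratio of the long-component weight to the total weight, in percent.
#'
#' @param a1 weight of the long (tubular fluid) component, >= 0
#' @param a2 weight of the short (parenchyma/blood) component, >= 0
#' @return `100 * a1 / (a1 + a2)`, between 0 and 100; vectorized over both
#'   arguments
#' @examples
#' tvfFromWeights(1, 1)  # 50
#' tvfFromWeights(1, 3)  # 25
#' @export
tvfFromWeights <- function(a1, a2) {
  if (any(a1 < 0) || any(a2 < 0)) stop("weights must be >= 0")
  tot <- a1 + a2
  if (any(tot == 0)) stop("a1 + a2 must be > 0")
  100 * a1 / tot
}

#' Reversible transverse relaxation time T2'
#'
#' The reversible (dephasing) component of the effective transverse
#' relaxation, defined by `1/T2* = 1/T2 + 1/T2'`, so
#' `T2' = 1 / (1/T2* - 1/T2)`.
#'
#' @param t2Ms irreversible transverse relaxation time T2 (ms)
#' @param t2StarMs effective transverse relaxation time T2* (ms); must be
#'   strictly smaller than `t2Ms` (equality would make T2' infinite)
#' @return T2' in ms; vectorized
#' @examples
#' t2prime(50, 10)  # 12.5
#' @export
t2prime <- function(t2Ms, t2StarMs) {
  if (any(t2Ms <= 0) || any(t2StarMs <= 0))
    stop("relaxation times must be > 0")
  if (any(t2StarMs >= t2Ms))
    stop("t2StarMs must be strictly smaller than t2Ms (T2* <= T2; equality gives undefined T2')")
  1 / (1 / t2StarMs - 1 / t2Ms)
}
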