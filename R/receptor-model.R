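#' @include AllClasses.R
NULL

# Package-level generator constants for the continuum mapping. These are
# design constants of the synthetic model, calibrated so that fast cells
# (c near 0) peak above 100 spk/s for 1-2 stimulus bursts while OFF cells
# (c near 1) pause for roughly 1-2 s after a 20 x 100 spk/s burst. They are
# tunable arguments of continuumParams(), not measured quantities.
CONTINUUM_DEFAULTS <- list(
  A_max = 110,   # spk/s: AMPAR weight of the fastest cell
  M1_max = 1000, # spk/s: mGluR1 weight at the fast pole (fades toward OFF)
  G2_max = 6,    # spk/s: mGluR2/3 weight of the most OFF-like cell
  R_max = 20,    # spk/s: spontaneous rate of the most OFF-like cell
  tau1_min = 0.3, tau1_max = 4  # s: mGluR1 kernel decay range
)

#' Map a continuum coordinate to receptor parameters
#'
#' Deterministic embedding of the fast-ON to slow-OFF UBC continuum into
#' [ReceptorParams-class]: the AMPAR weight falls linearly with `c`
#' (`aA = A_max (1 - c)`), the inhibitory mGluR2/3 weight and the spontaneous
#' rate rise linearly (`a2 = G2_max c`, `r0 = R_max c`; OFF cells are
#' spontaneously active), and the mGluR1 kernel decay interpolates
#' geometrically between `tau1_min` and `tau1_max`, so slow cells fire for
#' seconds after long bursts. The mGluR1 weight fades only near the OFF pole
#' (`a1 = M1_max (1 - c^2)`), reflecting the inverse expression of the mGluR1
#' and mGluR2 signaling pathways across the population: mGluR1-driven firing
#' is prominent throughout the excitatory continuum (its duration, set by
#' `tau1`, is what varies) and absent in pure OFF cells.
#'
#' @param c continuum coordinate in `[0, 1]` (0 = fast ON, 1 = slow OFF).
#' @param A_max,M1_max,G2_max,R_max,tau1_min,tau1_max generator constants
#'   (see Details); defaults are package constants.
#' @return A [ReceptorParams-class].
#' @examples
#' continuumParams(0)    # pure fast ON cell: a2 = 0, r0 = 0, maximal aA
#' continuumParams(1)    # OFF-dominated: aA = 0, maximal a2 and r0
#' @export
continuumParams <- function(c,
                            A_max = CONTINUUM_DEFAULTS$A_max,
                            M1_max = CONTINUUM_DEFAULTS$M1_max,
                            G2_max = CONTINUUM_DEFAULTS$G2_max,
                            R_max = CONTINUUM_DEFAULTS$R_max,
                            tau1_min = CONTINUUM_DEFAULTS$tau1_min,
                            tau1_max = CONTINUUM_DEFAULTS$tau1_max) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < 0 || c > 1)
    stop("continuum coordinate c must be a single value in [0, 1]")
  new("ReceptorParams",
      c = c,
      aA = A_max * (1 - c),
      a1 = M1_max * (1 - c^2),
      a2 = G2_max * c,
      r0 = R_max * c,
      tau1 = tau1_min * (tau1_max / tau1_min)^c)
}

#' Block a glutamate receptor
#'
#' Returns the parameter set with `receptor` added to the blocked set; the
#' blocked component contributes exactly zero to the intensity. Blocking is
#' idempotent and order-independent, mirroring cumulative antagonist wash-in
#' (LY341495 for mGluR2/3, NBQX for AMPAR, JNJ16259685 for mGluR1).
#'
#' @param params a [ReceptorParams-class].
#' @param receptor one of `"mGluR2/3"`, `"AMPAR"`, `"mGluR1"`.
#' @return A [ReceptorParams-class] with the receptor blocked.
#' @export
applyBlock <- function(params, receptor) {
  if (!is(params, "ReceptorParams")) stop("params must be ReceptorParams")
  if (length(receptor) != 1 || !receptor %in% c("mGluR2/3", "AMPAR", "mGluR1"))
    stop("unknown receptor: ", paste(receptor, collapse = ", "))
  params@blocked <- union(params@blocked, receptor)
  validObject(params)
  params
}

#' The cumulative antagonist wash-in series
#'
#' @param params a [ReceptorParams-class] (baseline stage).
#' @return Named list of four [ReceptorParams-class] stages:
#'   `baseline`, `mGluR2/3 blocked`, `+AMPAR`, `+mGluR1`.
#' @export
washInSeries <- function(params) {
  s1 <- applyBlock(params, "mGluR2/3")
  s2 <- applyBlock(s1, "AMPAR")
  s3 <- applyBlock(s2, "mGluR1")
  list(baseline = params, `mGluR2/3 blocked` = s1, `+AMPAR` = s2,
       `+mGluR1` = s3)
}

# Normalized difference-of-exponentials (unit peak) evaluated at lags >= 0.
alphaKernel <- function(lag, tauRise, tauDecay) {
  tStar <- tauRise * tauDecay / (tauDecay - tauRise) * log(tauDecay / tauRise)
  norm <- exp(-tStar / tauDecay) - exp(-tStar / tauRise)
  out <- numeric(length(lag))
  pos <- lag >= 0
  out[pos] <- (exp(-lag[pos] / tauDecay) - exp(-lag[pos] / tauRise)) / norm
  out
}

# Depression recursion: D[1] = 1;
# D[k+1] = 1 - (1 - D[k] * (1 - uDep)) * exp(-dt[k] / tauD)
depressionStates <- function(stimTimes, uDep, tauD) {
  n <- length(stimTimes)
  D <- numeric(n)
  if (!n) return(D)
  D[1] <- 1
  if (n > 1) for (k in seq_len(n - 1)) {
    dtk <- stimTimes[k + 1] - stimTimes[k]
    D[k + 1] <- 1 - (1 - D[k] * (1 - uDep)) * exp(-dtk / tauD)
  }
  D
}

#' Per-receptor component traces of the continuum model
#'
#' Evaluates each additive term of the conditional intensity separately, on a
#' uniform grid from `tStart` to `tStop`:
#' \itemize{
#'   \item `ampar`: \eqn{a_A \sum_k D_k \alpha(t - t_k)} -- unit-peak
#'     difference-of-exponentials kernel per stimulus, scaled by the
#'     short-term depression state \eqn{D_k};
#'   \item `mglur1`: \eqn{a_1 x_1(t)} where the glutamate signal \eqn{g(t)}
#'     jumps by 1 per stimulus and decays with `tauG`, is passed through a
#'     Hill nonlinearity \eqn{g^n / (g^n + K_g^n)} (so single stimuli build
#'     up too little glutamate to engage mGluR1), and is convolved with a
#'     unit-peak exponential kernel `tau1`. With this normalization the
#'     mGluR1 amplitude grows with the duration of suprathreshold glutamate
#'     (longer bursts recruit more mGluR1 drive) while its decay tracks the
#'     cell's kernel `tau1`;
#'   \item `mglur23`: \eqn{-a_2 \sum_k \beta(t - t_k)}, \eqn{\beta} a
#'     unit-peak exponential with decay `tau2` (inhibitory, hence negative).
#' }
#' Blocked receptors yield identically-zero traces. The optional AMPAR
#' `rebound` adds a slow post-burst bump after each annotated burst.
#'
#' @param params a [ReceptorParams-class].
#' @param pattern a [StimulusPattern-class].
#' @param gridDt grid step (s), must be <= 1 ms.
#' @param tStart,tStop trace extent (s); defaults to 0 and last stimulus + 10 s.
#' @return list with numeric vectors `t`, `ampar`, `mglur1`, `mglur23` and the
#'   scalar `r0`.
#' @export
componentTraces <- function(params, pattern, gridDt = 1e-3,
                            tStart = 0, tStop = NULL) {
  stopifnot(is(params, "ReceptorParams"), is(pattern, "StimulusPattern"))
  if (gridDt > 1e-3 + 1e-12) stop("gridDt must be <= 1 ms")
  stim <- stimulusTimes(pattern)
  if (is.null(tStop))
    tStop <- if (length(stim)) max(stim) + 10 else tStart + 10
  t <- seq(tStart, tStop, by = gridDt)
  n <- length(t)
  ampar <- numeric(n)
  mglur23 <- numeric(n)
  g <- numeric(n)

  if (length(stim)) {
    D <- depressionStates(stim, params@uDep, params@tauD)
    for (k in seq_along(stim)) {
      lag <- t - stim[k]
      pos <- lag >= 0
      if (!any(pos)) next
      ampar[pos] <- ampar[pos] +
        D[k] * alphaKernel(lag[pos], params@tauARise, params@tauADecay)
      mglur23[pos] <- mglur23[pos] + exp(-lag[pos] / params@tau2)
      g[pos] <- g[pos] + exp(-lag[pos] / params@tauG)
    }
    if (params@rebound) {
      # slow rebound current after each annotated burst as AMPARs recover
      # from desensitization during prolonged glutamate exposure
      ann <- annotations(pattern)
      bursts <- ann[ann$kind == "burst", , drop = FALSE]
      for (i in seq_len(nrow(bursts))) {
        inBurst <- stim >= bursts$t0[i] & stim < bursts$t1[i]
        if (sum(inBurst) < 5) next  # brief bursts desensitize too little
        endT <- max(stim[inBurst])
        lag <- t - endT
        pos <- lag >= 0
        ampar[pos] <- ampar[pos] +
          0.5 * sum(inBurst) / 20 * alphaKernel(lag[pos], 0.05, 0.4)
      }
    }
  }

  hill <- g^params@nHill / (g^params@nHill + params@Kg^params@nHill)
  # exact convolution of the piecewise-constant Hill drive with the
  # unit-peak kernel exp(-t / tau1)
  decay <- exp(-gridDt / params@tau1)
  x1 <- numeric(n)
  if (n > 1) for (i in seq_len(n - 1))
    x1[i + 1] <- x1[i] * decay + hill[i] * params@tau1 * (1 - decay)

  list(t = t,
       ampar = if ("AMPAR" %in% params@blocked) numeric(n)
               else params@aA * ampar,
       mglur1 = if ("mGluR1" %in% params@blocked) numeric(n)
                else params@a1 * x1,
       mglur23 = if ("mGluR2/3" %in% params@blocked) numeric(n)
                 else -params@a2 * mglur23,
       r0 = params@r0)
}

#' Conditional firing intensity of a model UBC
#'
#' \eqn{\lambda(t) = \max(0, r_0 + a_A x_A(t) + a_1 x_1(t) - a_2 x_2(t))}: the
#' receptor components of [componentTraces()] sum linearly and the result is
#' rectified at zero (the model's only nonlinearity after summation, so OFF
#' cell silencing is exact and superposition holds wherever the rate is
#' positive).
#'
#' @inheritParams componentTraces
#' @return A [RateTrace-class] (spk/s).
#' @examples
#' off <- continuumParams(1)
#' lam <- responseIntensity(off, makeBurstPattern(20, 100, t0 = 1))
#' min(rateValues(lam))  # silenced after the burst
#' @export
responseIntensity <- function(params, pattern, gridDt = 1e-3,
                              tStart = 0, tStop = NULL) {
  comp <- componentTraces(params, pattern, gridDt, tStart, tStop)
  lam <- pmax(0, comp$r0 + comp$ampar + comp$mglur1 + comp$mglur23)
  RateTrace(lam, t0 = comp$t[1], dt = gridDt)
}

#' Sample spike trains from an intensity trace
#'
#' Inhomogeneous Poisson sampling by thinning, with an absolute refractory
#' period enforced on accepted spikes. Each trial uses its own RNG substream
#' derived from `(seed, trial index)`, so any single trial is reproducible in
#' isolation.
#'
#' @param intensity a [RateTrace-class] (spk/s, >= 0).
#' @param tRef absolute refractory period (s).
#' @param nTrials number of trials (>= 1).
#' @param seed integer seed.
#' @return list of `nTrials` [SpikeTrain-class] objects spanning the trace.
#' @export
sampleTrials <- function(intensity, tRef = 0.002, nTrials = 1, seed = 1) {
  stopifnot(is(intensity, "RateTrace"), nTrials >= 1, tRef >= 0)
  vv <- rateValues(intensity)
  tt <- rateTimes(intensity)
  t0 <- tt[1]
  t1 <- tt[length(tt)]
  lamMax <- max(vv, 0)
  lapply(seq_len(nTrials), function(i) {
    spikes <- withr::with_seed(trialSeed(seed, i), {
      if (lamMax <= 0) numeric(0) else {
        nCand <- stats::rpois(1, lamMax * (t1 - t0))
        cand <- sort(stats::runif(nCand, t0, t1))
        keep <- stats::runif(nCand) < traceAt(intensity, cand) / lamMax
        cand <- cand[keep]
        if (tRef > 0 && length(cand) > 1) {
          acc <- numeric(0)
          last <- -Inf
          for (s in cand) {
            if (s - last >= tRef) { acc <- c(acc, s); last <- s }
          }
          cand <- acc
        }
        cand
      }
    })
    SpikeTrain(spikes, trialId = i - 1L, tStart = t0, tStop = t1 + 1e-9)
  })
}

#' Simulate a cohort of UBC recordings across the continuum
#'
#' Generates `n` model cells with continuum coordinates evenly spaced on
#' `[0, 1]`, evaluates each cell's intensity for the given stimulus pattern,
#' and samples `nTrials` spike trains per cell.
#'
#' @param pattern a [StimulusPattern-class].
#' @param n number of cells.
#' @param cValues continuum coordinates (defaults to `n` evenly spaced).
#' @param nTrials trials per cell.
#' @param seed integer seed; cell `i` uses substreams of `seed + i`.
#' @param gridDt intensity grid (s).
#' @param blocked receptors blocked in every cell (wash-in stage).
#' @param tStart start of the simulated window (s, may precede the first
#'   stimulus to provide a baseline period).
#' @return list with elements `recordings` (list of [CellRecording-class]),
#'   `params` (list of [ReceptorParams-class]) and `cValues`.
#' @export
simulateCohort <- function(pattern, n = 31, cValues = seq(0, 1, length.out = n),
                           nTrials = 8, seed = 1, gridDt = 1e-3,
                           blocked = character(0), tStart = 0) {
  params <- lapply(cValues, function(cc) {
    p <- continuumParams(cc)
    for (r in blocked) p <- applyBlock(p, r)
    p
  })
  recordings <- lapply(seq_along(params), function(i) {
    lam <- responseIntensity(params[[i]], pattern, gridDt, tStart = tStart)
    tr <- sampleTrials(lam, tRef = params[[i]]@tRef, nTrials = nTrials,
                       seed = seed + i)
    CellRecording(cellId = sprintf("sim%02d", i), trials = tr,
                  stimulus = pattern, condition = blocked)
  })
  list(recordings = recordings, params = params, cValues = cValues)
}
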