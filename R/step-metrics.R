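#' @include AllClasses.R
NULL

#' Spikes evoked during and after a rate step
#'
#' Baseline-corrected spike counts for a 1 s step change in input rate: the
#' reference rate is the mean over the 1 s preceding the step,
#' `spikes_during` integrates the step period `[stepOnset, stepOffset)` minus
#' the reference expectation, and `spikes_after` integrates the 3 s after the
#' step likewise. Negative values mean the step suppressed firing.
#'
#' @param trace a [RateTrace-class] covering
#'   `[stepOnset - 1, stepOffset + 3)`.
#' @param stepOnset,stepOffset step window (s).
#' @return list with `spikes_during`, `spikes_after` and `reference_rate`.
#' @export
stepSpikeChanges <- function(trace, stepOnset, stepOffset) {
  stopifnot(is(trace, "RateTrace"), stepOffset > stepOnset)
  tt <- rateTimes(trace)
  if (tt[1] > stepOnset - 1 + 1e-9 || tt[length(tt)] < stepOffset + 3 - 1e-9)
    stop("trace must cover [stepOnset - 1, stepOffset + 3)")
  ref <- traceMean(trace, stepOnset - 1, stepOnset)
  during <- traceIntegral(trace, stepOnset, stepOffset) -
    ref * (stepOffset - stepOnset)
  after <- traceIntegral(trace, stepOffset, stepOffset + 3) - ref * 3
  list(spikes_during = during, spikes_after = after, reference_rate = ref)
}

#' Excise single-stimulus transients from a rate trace
#'
#' Replaces the samples in `[t_k, t_k + excisionWindow)` after each baseline
#' stimulus by linear interpolation between the last sample before the window
#' and the first sample after it; overlapping excision windows are merged.
#' Used before measuring slow step-response decay, so discrete responses to
#' individual baseline stimuli do not masquerade as slow firing. Idempotent.
#'
#' @param trace a [RateTrace-class].
#' @param baselineStimulusTimes stimulus times whose transients to remove (s).
#' @param excisionWindow window length after each stimulus (s), > 0.
#' @return A [RateTrace-class] with transients interpolated away.
#' @export
removeStimulusTransients <- function(trace, baselineStimulusTimes,
                                     excisionWindow = 0.1) {
  stopifnot(is(trace, "RateTrace"), excisionWindow > 0)
  if (!length(baselineStimulusTimes)) return(trace)
  tt <- rateTimes(trace)
  vv <- rateValues(trace)
  st <- sort(baselineStimulusTimes)
  # merge overlapping [t_k, t_k + w) windows
  starts <- ends <- numeric(0)
  curS <- st[1]; curE <- st[1] + excisionWindow
  for (s in st[-1]) {
    if (s <= curE) curE <- s + excisionWindow
    else { starts <- c(starts, curS); ends <- c(ends, curE)
           curS <- s; curE <- s + excisionWindow }
  }
  starts <- c(starts, curS); ends <- c(ends, curE)
  for (i in seq_along(starts)) {
    idx <- which(tt >= starts[i] & tt < ends[i])
    if (!length(idx)) next
    lo <- min(idx) - 1
    hi <- max(idx) + 1
    if (lo < 1 || hi > length(tt)) next  # window touches the trace edge
    vv[idx] <- vv[lo] + (vv[hi] - vv[lo]) *
      (tt[idx] - tt[lo]) / (tt[hi] - tt[lo])
  }
  RateTrace(vv, t0 = trace@t0, dt = trace@dt)
}

lognormalModel <- function(t, A, mu, sigma) {
  A * exp(-((log(t) - mu) / sigma)^2)
}

#' Log-normal fit of a step response's time to peak
#'
#' Fits the baseline-subtracted rate against time since step onset with
#' \deqn{A \exp\{-[(\ln t - \mu)/\sigma]^2\}} by Levenberg-Marquardt least
#' squares, using multi-start initialization of \eqn{\mu} over a logarithmic
#' grid. The fitted time to peak is \eqn{e^{\mu}}. The fit is marked invalid
#' (`fit_ok = FALSE`) when the response peak is below `minPeakChange` (cells
#' without a significant increase in firing after the step) or when no start
#' converges.
#'
#' @param trace a [RateTrace-class] covering `[stepOnset, stepOnset + fitWindow)`.
#' @param stepOnset step onset (s).
#' @param fitWindow fit window length (s).
#' @param baseline baseline rate to subtract (spk/s).
#' @param minPeakChange significance threshold on the baseline-corrected peak
#'   (spk/s); default 8 spk/s, the same threshold used to sort the population.
#' @return list with `A`, `mu`, `sigma`, `time_to_peak`, `fit_ok` and the
#'   residual sum of squares `rss`.
#' @export
fitLognormalPeak <- function(trace, stepOnset, fitWindow = 3, baseline = 0,
                             minPeakChange = 8) {
  stopifnot(is(trace, "RateTrace"), fitWindow > 0)
  tt <- rateTimes(trace)
  sel <- tt > stepOnset + trace@dt / 2 & tt < stepOnset + fitWindow
  x <- tt[sel] - stepOnset     # t > 0 only: ln t singularity at 0
  y <- rateValues(trace)[sel] - baseline
  bad <- list(A = NA_real_, mu = NA_real_, sigma = NA_real_,
              time_to_peak = NA_real_, fit_ok = FALSE, rss = NA_real_)
  if (length(x) < 5 || max(y) < minPeakChange) return(bad)

  muGrid <- seq(log(0.02), log(fitWindow * 0.8), length.out = 8)
  best <- NULL
  for (mu0 in muGrid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-((log(x) - mu) / sigma)^2),
        start = list(A = max(y), mu = mu0, sigma = 0.5),
        lower = c(A = 1e-6, mu = log(1e-4), sigma = 1e-3),
        upper = c(A = 10 * max(y), mu = log(100), sigma = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit)), rss = rss)
  }
  if (is.null(best)) return(bad)
  list(A = best$A, mu = best$mu, sigma = abs(best$sigma),
       time_to_peak = exp(best$mu), fit_ok = TRUE, rss = best$rss)
}

#' Half-decay time of a step response
#'
#' First time after the response peak at which the (transient-excised) rate
#' falls to halfway between peak and baseline, reported relative to the step
#' offset (negative values are clamped to 0, for peaks that decay before the
#' step ends). NA with attribute `no_crossing` when the rate never decays by
#' half within the trace.
#'
#' @param trace a [RateTrace-class], ideally already passed through
#'   [removeStimulusTransients()].
#' @param peakTime time of the response peak (s).
#' @param peakRate peak rate (spk/s), must exceed `baseline`.
#' @param baseline baseline rate (spk/s).
#' @param stepOffset step offset the result is referenced to (s); defaults to
#'   `peakTime` (i.e. decay measured from the peak).
#' @return Half-decay time (s) or NA.
#' @export
halfDecayTime <- function(trace, peakTime, peakRate, baseline = 0,
                          stepOffset = peakTime) {
  stopifnot(is(trace, "RateTrace"), peakRate > baseline)
  thr <- baseline + (peakRate - baseline) / 2
  crossing <- firstTimeAtOrBelow(trace, thr, from = peakTime)
  if (is.na(crossing))
    return(structure(NA_real_, no_crossing = TRUE))
  max(0, crossing - stepOffset)
}
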