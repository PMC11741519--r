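#' @include AllClasses.R
NULL

#' Burst-response metrics of a rate trace
#'
#' Implements the standard per-cell quantification of a burst response:
#' \itemize{
#'   \item `baseline_rate`: mean rate over the 1 s preceding stimulation,
#'     `[stimOnset - 1, stimOnset)`;
#'   \item `peak_rate` / `peak_change`: maximum rate in the search window
#'     after the end of stimulation, `(stimEnd, stimEnd + tSearch]`, and its
#'     baseline-corrected value;
#'   \item `half_width`: time between the first up-crossing and the first
#'     subsequent down-crossing of `baseline + peak_change / 2` (linear
#'     interpolation between grid samples); undefined unless
#'     `peak_change > 0` and both crossings exist;
#'   \item `pause_duration`: time from `stimEnd` until the rate first reaches
#'     `min(5, peak_rate / 2)` spk/s; 0 when the rate never drops below that
#'     threshold after `stimEnd`, and undefined (NA) for cells that do not
#'     fire at baseline, for which "recovery" is meaningless;
#'   \item `response_start`: first time after `stimOnset` the rate exceeds
#'     `baseline + responseStartFrac * peak_change` (used to anchor the
#'     evoked-spike integration window).
#' }
#'
#' @param trace a [RateTrace-class] covering at least
#'   `[stimOnset - 1, stimEnd + tSearch]`.
#' @param stimOnset,stimEnd first and last stimulus time of the burst (s).
#' @param tSearch peak search window after `stimEnd` (s).
#' @param responseStartFrac fraction of `peak_change` defining response onset.
#' @param includeStimPeriod logical; also search the stimulation period itself
#'   for the peak (off by default: the peak is taken after stimulation ends).
#' @return Named list with elements `baseline_rate`, `peak_rate`,
#'   `peak_change`, `half_width`, `pause_duration`, `evoked_spikes` (NA here;
#'   see [evokedSpikeCount()]), `response_start`.
#' @export
burstResponseMetrics <- function(trace, stimOnset, stimEnd, tSearch = 4,
                                 responseStartFrac = 0.1,
                                 includeStimPeriod = FALSE) {
  stopifnot(is(trace, "RateTrace"))
  tt <- rateTimes(trace)
  tEnd <- tt[length(tt)]
  if (tt[1] > stimOnset - 1 + 1e-9)
    stop("trace must cover the 1 s baseline window before stimulation")
  tSearch <- min(tSearch, tEnd - stimEnd)
  if (tSearch <= 0)
    stop("trace must extend past the end of stimulation")

  baseline <- traceMean(trace, stimOnset - 1, stimOnset)

  searchFrom <- if (includeStimPeriod) stimOnset else stimEnd
  inWin <- tt > searchFrom & tt <= stimEnd + tSearch
  peakRate <- max(rateValues(trace)[inWin])
  peakTime <- tt[inWin][which.max(rateValues(trace)[inWin])]
  peakChange <- peakRate - baseline

  halfWidth <- NA_real_
  responseStart <- NA_real_
  if (peakChange > 0) {
    # full width at half maximum of the peak-containing lobe: last up-crossing
    # of the half level before the peak, first down-crossing after it (robust
    # when an early during-burst transient precedes the main response)
    thrHalf <- baseline + peakChange / 2
    pre <- tt >= stimOnset & tt <= peakTime
    vPre <- rateValues(trace)[pre]
    tPre <- tt[pre]
    below <- which(vPre < thrHalf)
    up <- if (!length(below)) {
      firstTimeAtOrAbove(trace, thrHalf, from = stimOnset)
    } else {
      i <- below[length(below)]
      if (i == length(vPre)) NA_real_
      else tPre[i] + (thrHalf - vPre[i]) / (vPre[i + 1] - vPre[i]) *
        (tPre[i + 1] - tPre[i])
    }
    if (!is.na(up)) {
      down <- firstTimeAtOrBelow(trace, thrHalf, from = peakTime)
      if (!is.na(down)) halfWidth <- down - up
    }
    responseStart <- firstTimeAtOrAbove(
      trace, baseline + responseStartFrac * peakChange, from = stimOnset)
  }

  # pause presupposes recovery of baseline firing: undefined for silent cells
  pause <- NA_real_
  if (baseline > 0) {
    theta <- min(5, peakRate / 2)
    after <- rateValues(trace)[tt >= stimEnd]
    if (!length(after) || min(after) >= theta) {
      pause <- 0
    } else {
      rec <- firstTimeAtOrAbove(trace, theta, from = stimEnd)
      pause <- if (is.na(rec)) NA_real_ else rec - stimEnd
    }
  }

  list(baseline_rate = baseline, peak_rate = peakRate,
       peak_change = peakChange, half_width = halfWidth,
       pause_duration = pause, evoked_spikes = NA_real_,
       response_start = responseStart)
}

#' Baseline-corrected evoked spike count
#'
#' Integrates the rate trace (trapezoid rule) from the start of stimulation
#' until two half-widths after the response start, and subtracts the expected
#' baseline spike count over the same window. When the half-width is
#' undefined, a fallback 2 s window after `stimOnset` is integrated and the
#' result is flagged (`attr(x, "fallback")`); a window reaching past the
#' trace is truncated and flagged (`attr(x, "truncated")`).
#'
#' @param trace a [RateTrace-class].
#' @param stimOnset start of stimulation (s).
#' @param responseStart response onset (s), from [burstResponseMetrics()].
#' @param halfWidth half-width (s) or NA.
#' @param baselineRate baseline firing rate (spk/s).
#' @return Numeric evoked-spike count (may be negative for suppressed cells).
#' @export
evokedSpikeCount <- function(trace, stimOnset, responseStart, halfWidth,
                             baselineRate) {
  stopifnot(is(trace, "RateTrace"))
  fallback <- is.na(halfWidth) || is.na(responseStart)
  winEnd <- if (fallback) stimOnset + 2 else responseStart + 2 * halfWidth
  tt <- rateTimes(trace)
  tMax <- tt[length(tt)]
  truncated <- winEnd > tMax
  if (truncated) winEnd <- tMax
  if (winEnd <= stimOnset) return(structure(0, truncated = truncated,
                                            fallback = fallback))
  count <- traceIntegral(trace, stimOnset, winEnd) -
    baselineRate * (winEnd - stimOnset)
  structure(count, fallback = fallback, truncated = truncated)
}

#' Per-stimulus response during constant-rate stimulation
#'
#' For constant 1-5 spk/s input, averages the stimulus-aligned response
#' segments `[t_k, t_k + window)` over all stimuli excluding the first five,
#' pointwise across trials and stimuli, and returns the peak and time
#' integral (spikes per stimulus) of the mean segment. Deliberately not
#' baseline-corrected.
#'
#' @param traceList list of per-trial [RateTrace-class] on a common grid.
#' @param stimulusTimes constant-rate stimulus times (s), at least 6.
#' @param window segment length (s), at most the inter-stimulus interval.
#' @return list with `mean_segment` (a [RateTrace-class] on time-since-
#'   stimulus), `peak_rate` (spk/s) and `spikes_per_stimulus`.
#' @export
constantRateResponse <- function(traceList, stimulusTimes, window) {
  if (length(stimulusTimes) < 6)
    stop("constant-rate analysis needs at least 6 stimuli (first 5 excluded)")
  stopifnot(window > 0, length(traceList) >= 1)
  used <- stimulusTimes[-(1:5)]
  dt <- traceList[[1]]@dt
  rel <- seq(0, window - dt / 2, by = dt)
  segs <- lapply(traceList, function(tr) {
    rowMeans(vapply(used, function(tk) traceAt(tr, tk + rel),
                    numeric(length(rel))))
  })
  meanSeg <- Reduce(`+`, segs) / length(segs)
  segTrace <- RateTrace(meanSeg, t0 = 0, dt = dt)
  list(mean_segment = segTrace,
       peak_rate = max(meanSeg),
       spikes_per_stimulus = pracma::trapz(rel, meanSeg))
}
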