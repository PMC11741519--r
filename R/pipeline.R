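#' @include AllClasses.R
NULL

burstWindow <- function(pattern) {
  stim <- stimulusTimes(pattern)
  if (!length(stim)) stop("pattern has no stimuli")
  c(onset = stim[1], end = stim[length(stim)])
}

#' Full burst quantification of one recording
#'
#' Chains the standard pipeline for a burst protocol: per-trial reciprocal-ISI
#' rates, per-trial median filtering, trial averaging, then the
#' burst-response metrics and the baseline-corrected evoked-spike count.
#'
#' @param recording a [CellRecording-class] whose stimulus is a single burst.
#' @param dt rate grid (s).
#' @param medianWindow per-trial running-median width (samples).
#' @param tSearch peak-search window after the burst (s).
#' @return One-row data.frame: identifiers plus `baseline_rate`, `peak_rate`,
#'   `peak_change`, `half_width`, `pause_duration`, `evoked_spikes`,
#'   `response_start`.
#' @export
analyzeBurstRecording <- function(recording, dt = 1e-3, medianWindow = 3,
                                  tSearch = 4) {
  stopifnot(is(recording, "CellRecording"), length(recording@trials) >= 1)
  win <- burstWindow(recording@stimulus)
  trace <- preprocessTrials(recording@trials, dt = dt,
                            medianWindow = medianWindow)
  m <- burstResponseMetrics(trace, win["onset"], win["end"],
                            tSearch = tSearch)
  m$evoked_spikes <- as.numeric(evokedSpikeCount(
    trace, win["onset"], m$response_start, m$half_width, m$baseline_rate))
  data.frame(cell_id = recording@cellId,
             protocol_id = recording@protocolId,
             condition = formatCondition(recording@condition),
             as.data.frame(m[c("baseline_rate", "peak_rate", "peak_change",
                               "half_width", "pause_duration",
                               "evoked_spikes", "response_start")]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Burst metrics table for a cohort of recordings
#'
#' @param recordings list of [CellRecording-class] objects sharing a protocol.
#' @param ... passed to [analyzeBurstRecording()].
#' @return data.frame, one row per recording, ready for [sortPopulation()].
#' @export
burstMetricsTable <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, analyzeBurstRecording, ...))
}

#' Step-response quantification of one rate trace
#'
#' For each `step` annotation of the protocol: baseline-referenced spike
#' counts during and for 3 s after the step ([stepSpikeChanges()]); for the
#' highest-rate step additionally the log-normal time-to-peak fit and the
#' half-decay time on a transient-excised trace.
#'
#' @param trace a [RateTrace-class] for the whole step protocol.
#' @param pattern the step [StimulusPattern-class] (annotations required).
#' @param excisionWindow window excised after each baseline stimulus (s).
#' @param fitWindow log-normal fit window after step onset (s).
#' @return data.frame with one row per step: `step_rate`, `spikes_during`,
#'   `spikes_after`, and for the highest step `A`, `mu`, `sigma`,
#'   `time_to_peak`, `half_decay`, `fit_ok`.
#' @export
analyzeStepTrace <- function(trace, pattern, excisionWindow = 0.1,
                             fitWindow = 3) {
  ann <- annotations(pattern)
  steps <- ann[ann$kind == "step", , drop = FALSE]
  if (!nrow(steps)) stop("pattern has no step annotations")
  steps <- steps[order(steps$t0), , drop = FALSE]
  stim <- stimulusTimes(pattern)
  inStep <- rep(FALSE, length(stim))
  for (i in seq_len(nrow(steps)))
    inStep <- inStep | (stim >= steps$t0[i] & stim < steps$t1[i])
  baseStim <- stim[!inStep]

  rows <- lapply(seq_len(nrow(steps)), function(i) {
    on <- steps$t0[i]; off <- steps$t1[i]
    sc <- stepSpikeChanges(trace, on, off)
    out <- data.frame(step_rate = steps$nominal_rate[i],
                      spikes_during = sc$spikes_during,
                      spikes_after = sc$spikes_after,
                      A = NA_real_, mu = NA_real_, sigma = NA_real_,
                      time_to_peak = NA_real_, half_decay = NA_real_,
                      fit_ok = FALSE)
    if (steps$nominal_rate[i] == max(steps$nominal_rate)) {
      fit <- fitLognormalPeak(trace, on, fitWindow = fitWindow,
                              baseline = sc$reference_rate)
      out$A <- fit$A; out$mu <- fit$mu; out$sigma <- fit$sigma
      out$time_to_peak <- fit$time_to_peak; out$fit_ok <- fit$fit_ok
      if (fit$fit_ok) {
        exc <- removeStimulusTransients(trace, baseStim, excisionWindow)
        tt <- rateTimes(exc)
        sel <- tt > on & tt <= off + fitWindow
        peakIdx <- which(sel)[which.max(rateValues(exc)[sel])]
        out$half_decay <- halfDecayTime(
          exc, peakTime = tt[peakIdx],
          peakRate = rateValues(exc)[peakIdx],
          baseline = min(sc$reference_rate,
                         rateValues(exc)[peakIdx] - 1e-6),
          stepOffset = off)
      }
    }
    out
  })
  do.call(rbind, rows)
}
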