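#' @include AllClasses.R
NULL

#' Build a regular high-frequency mossy fiber burst
#'
#' Stimuli at `t0 + k / rate` for `k = 0 .. nStimuli - 1`, annotated as a
#' single `burst` interval. The standard categorization burst is 20 stimuli at
#' 100 spk/s; single stimuli are the `nStimuli = 1` case.
#'
#' @param nStimuli number of stimuli in the burst (>= 1).
#' @param rate intra-burst rate (spk/s, > 0).
#' @param t0 time of the first stimulus (s).
#' @param protocolId protocol label; defaults to e.g. `"burst20x100"`.
#' @return A [StimulusPattern-class].
#' @examples
#' makeBurstPattern(20, 100)          # 0, 0.01, ..., 0.19 s
#' makeBurstPattern(1, 100, t0 = 2)   # a single stimulus at 2 s
#' @export
makeBurstPattern <- function(nStimuli, rate, t0 = 0,
                             protocolId = sprintf("burst%dx%g", nStimuli, rate)) {
  stopifnot(nStimuli >= 1, rate > 0, t0 >= 0)
  times <- t0 + (seq_len(nStimuli) - 1) / rate
  ann <- data.frame(kind = "burst", t0 = t0,
                    t1 = t0 + (nStimuli - 1) / rate + 1e-6,
                    nominal_rate = rate, stringsAsFactors = FALSE)
  StimulusPattern(times, ann, protocolId)
}

#' Build a smooth-pursuit-like step protocol
#'
#' A regular baseline train (default 5 spk/s) interposed with `stepDuration`-s
#' constant-rate steps, one per entry of `stepRates`, with step onsets spaced
#' `interval` seconds apart after an initial baseline period of the same
#' length. During a step, stimuli run at the step rate phase-aligned to the
#' step onset; outside steps the baseline keeps its own grid (multiples of
#' `1/baselineRate` from time 0). Steps carry `step` annotations with the
#' nominal rate; baseline stretches are annotated `baseline`.
#'
#' @param baselineRate baseline stimulation rate (spk/s, >= 0; 0 = no baseline
#'   stimuli).
#' @param stepRates vector of step rates (spk/s), each > `baselineRate`.
#' @param stepDuration step length (s), must be < `interval`.
#' @param interval onset-to-onset spacing of consecutive steps (s).
#' @param tail baseline time appended after the last step (s).
#' @param protocolId protocol label.
#' @return A [StimulusPattern-class].
#' @examples
#' sp <- makeStepProtocol(5, c(10, 20, 30, 40, 50, 60), 1, 4)
#' subset(annotations(sp), kind == "step")
#' @export
makeStepProtocol <- function(baselineRate = 5,
                             stepRates = c(10, 20, 30, 40, 50, 60),
                             stepDuration = 1, interval = 4, tail = interval,
                             protocolId = "steps") {
  stopifnot(baselineRate >= 0, all(stepRates > baselineRate),
            stepDuration > 0, interval > 0)
  if (stepDuration >= interval)
    stop("stepDuration must be smaller than the step interval")
  nSteps <- length(stepRates)
  onsets <- interval + (seq_len(nSteps) - 1) * interval
  total <- if (nSteps) onsets[nSteps] + stepDuration + tail else interval + tail

  base <- if (baselineRate > 0)
    seq(0, total - 1e-9, by = 1 / baselineRate) else numeric(0)
  times <- base
  ann <- emptyAnnotations()
  cursor <- 0
  for (i in seq_len(nSteps)) {
    on <- onsets[i]; off <- on + stepDuration
    nStim <- round(stepRates[i] * stepDuration)
    stepStim <- on + (seq_len(nStim) - 1) / stepRates[i]
    # baseline keeps out of the step window; resumes on its own grid after
    times <- times[times < on - 1e-9 | times >= off - 1e-9]
    times <- sort(unique(c(times, stepStim)))
    if (on > cursor)
      ann <- rbind(ann, data.frame(kind = "baseline", t0 = cursor, t1 = on,
                                   nominal_rate = baselineRate))
    ann <- rbind(ann, data.frame(kind = "step", t0 = on, t1 = off,
                                 nominal_rate = stepRates[i]))
    cursor <- off
  }
  if (total > cursor)
    ann <- rbind(ann, data.frame(kind = "baseline", t0 = cursor, t1 = total,
                                 nominal_rate = baselineRate))
  StimulusPattern(times, ann, protocolId)
}

#' Build an in-vivo-like train of high-frequency bursts
#'
#' Burst onsets follow a seeded renewal process whose inter-onset interval is
#' a dead time (long enough for the largest burst) plus an exponential
#' variate, calibrated so the expected number of bursts is
#' `duration * burstRate`. Burst sizes are uniform integers on
#' `burstSizeRange`; within a burst, stimuli run at `intraBurstRate`. This
#' emulates mossy fibers that fire in brief very-high-frequency bursts of
#' 2-23 spikes during pursuit eye movements.
#'
#' @param duration train length (s).
#' @param burstSizeRange integer `c(min, max)` spikes per burst, `2 <= min <= max`.
#' @param intraBurstRate within-burst rate (spk/s).
#' @param burstRate mean burst frequency (bursts/s).
#' @param seed integer seed; fixed seed gives an identical pattern.
#' @param protocolId protocol label.
#' @return A [StimulusPattern-class] with one `burst` annotation per burst.
#' @export
makeInvivoBurstTrain <- function(duration, burstSizeRange = c(2, 23),
                                 intraBurstRate = 300, burstRate = 0.5,
                                 seed = 1, protocolId = "invivo") {
  stopifnot(duration > 0, length(burstSizeRange) == 2,
            burstSizeRange[1] >= 2, burstSizeRange[1] <= burstSizeRange[2],
            intraBurstRate > 0, burstRate > 0)
  dead <- (burstSizeRange[2] - 1) / intraBurstRate + 0.05
  meanGap <- 1 / burstRate
  if (meanGap <= dead)
    stop("burstRate too high for the burst duration (overlapping bursts)")
  withr::with_seed(trialSeed(seed, 0L), {
    onsets <- numeric(0)
    t <- dead + stats::rexp(1, rate = 1 / (meanGap - dead))
    # first onset drawn like an ordinary renewal interval from time 0
    while (t < duration) {
      onsets <- c(onsets, t)
      t <- t + dead + stats::rexp(1, rate = 1 / (meanGap - dead))
    }
    sizes <- if (burstSizeRange[1] == burstSizeRange[2])
      rep(burstSizeRange[1], length(onsets))
    else
      sample(burstSizeRange[1]:burstSizeRange[2], length(onsets),
             replace = TRUE)
  })
  times <- unlist(lapply(seq_along(onsets), function(i)
    onsets[i] + (seq_len(sizes[i]) - 1) / intraBurstRate))
  ann <- if (length(onsets))
    data.frame(kind = "burst", t0 = onsets,
               t1 = onsets + (sizes - 1) / intraBurstRate + 1e-6,
               nominal_rate = intraBurstRate, stringsAsFactors = FALSE)
  else emptyAnnotations()
  StimulusPattern(times, ann, protocolId)
}
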