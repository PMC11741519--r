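#' @include AllClasses.R
NULL

#' Stimulus times of a pattern
#' @param x a [StimulusPattern-class].
#' @return numeric vector of stimulus times (s).
#' @export
setGeneric("stimulusTimes", function(x) standardGeneric("stimulusTimes"))

#' @rdname stimulusTimes
#' @export
setMethod("stimulusTimes", "StimulusPattern", function(x) x@times)

#' Interval annotations of a stimulus pattern
#' @param x a [StimulusPattern-class].
#' @return data.frame with columns `kind`, `t0`, `t1`, `nominal_rate`.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname annotations
#' @export
setMethod("annotations", "StimulusPattern", function(x) x@annotations)

#' Spike times of a trial
#' @param x a [SpikeTrain-class].
#' @return numeric vector of spike times (s).
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' Protocol identifier
#' @param x a [StimulusPattern-class] or [CellRecording-class].
#' @return single character.
#' @export
setGeneric("protocolId", function(x) standardGeneric("protocolId"))

#' @rdname protocolId
#' @export
setMethod("protocolId", "StimulusPattern", function(x) x@protocolId)

#' @rdname protocolId
#' @export
setMethod("protocolId", "CellRecording", function(x) x@protocolId)

#' Cell identifier
#' @param x a [CellRecording-class].
#' @return single character.
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname cellId
#' @export
setMethod("cellId", "CellRecording", function(x) x@cellId)

#' Trials of a recording
#' @param x a [CellRecording-class].
#' @return list of [SpikeTrain-class] objects.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname trials
#' @export
setMethod("trials", "CellRecording", function(x) x@trials)

#' Blocked-receptor condition of a recording or parameter set
#' @param x a [CellRecording-class] or [ReceptorParams-class].
#' @return character vector of blocked receptors (empty = baseline).
#' @export
setGeneric("blockedReceptors", function(x) standardGeneric("blockedReceptors"))

#' @rdname blockedReceptors
#' @export
setMethod("blockedReceptors", "CellRecording", function(x) x@condition)

#' @rdname blockedReceptors
#' @export
setMethod("blockedReceptors", "ReceptorParams", function(x) x@blocked)

#' Grid times of a rate trace
#' @param x a [RateTrace-class].
#' @return numeric vector of sample times (s).
#' @export
setGeneric("rateTimes", function(x) standardGeneric("rateTimes"))

#' @rdname rateTimes
#' @export
setMethod("rateTimes", "RateTrace",
          function(x) x@t0 + (seq_along(x@values) - 1) * x@dt)

#' Rate values of a trace
#' @param x a [RateTrace-class].
#' @return numeric vector (spk/s).
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))

#' @rdname rateValues
#' @export
setMethod("rateValues", "RateTrace", function(x) x@values)

setMethod("show", "StimulusPattern", function(object) {
  cat(sprintf("StimulusPattern '%s': %d stimuli", object@protocolId,
              length(object@times)))
  if (length(object@times))
    cat(sprintf(" on [%.3f, %.3f] s", object@times[1], max(object@times)))
  ann <- object@annotations
  if (nrow(ann)) {
    tab <- table(ann$kind)
    cat(sprintf("; annotations: %s",
                paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain trial %d: %d spikes on [%.3f, %.3f) s\n",
              object@trialId, length(object@times), object@tStart,
              object@tStop))
})

setMethod("show", "CellRecording", function(object) {
  cond <- if (length(object@condition))
    paste(object@condition, collapse = "+") else "baseline"
  cat(sprintf("CellRecording '%s' / protocol '%s' / %s: %d trials, %d spikes\n",
              object@cellId, object@protocolId, cond, length(object@trials),
              sum(vapply(object@trials, function(x) length(x@times),
                         integer(1)))))
})

setMethod("show", "RateTrace", function(object) {
  n <- length(object@values)
  cat(sprintf("RateTrace: %d samples, dt = %g s, span [%.3f, %.3f) s, peak %.1f spk/s\n",
              n, object@dt, object@t0, object@t0 + n * object@dt,
              if (n) max(object@values) else NA_real_))
})

setMethod("show", "ReceptorParams", function(object) {
  cat(sprintf(
    "ReceptorParams (c = %.2f): r0 = %.1f, aA = %.1f, a1 = %.1f, a2 = %.1f spk/s; tau1 = %.2f s",
    object@c, object@r0, object@aA, object@a1, object@a2, object@tau1))
  if (length(object@blocked))
    cat(sprintf("; blocked: %s", paste(object@blocked, collapse = "+")))
  cat("\n")
})
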