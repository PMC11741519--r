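#' @import methods
NULL

RECEPTOR_NAMES <- c("mGluR2/3", "AMPAR", "mGluR1", "NMDAR")
ANNOTATION_KINDS <- c("burst", "step", "baseline")

emptyAnnotations <- function() {
  data.frame(kind = character(0), t0 = numeric(0), t1 = numeric(0),
             nominal_rate = numeric(0), stringsAsFactors = FALSE)
}

#' StimulusPattern: ordered mossy fiber stimulus times with protocol annotations
#'
#' Holds the times (seconds) at which the presynaptic mossy fiber is driven,
#' together with labeled half-open intervals `[t0, t1)` marking bursts, rate
#' steps and baseline stretches, and the nominal stimulation rate of each.
#'
#' @slot times numeric, strictly increasing stimulus times in seconds, all >= 0.
#' @slot annotations data.frame with columns `kind` (one of `"burst"`,
#'   `"step"`, `"baseline"`), `t0`, `t1` (seconds, half-open interval) and
#'   `nominal_rate` (spk/s, `NA` allowed).
#' @slot protocolId single character protocol label.
#'
#' @seealso [makeBurstPattern()], [makeStepProtocol()], [makeInvivoBurstTrain()]
#' @export
setClass("StimulusPattern",
  representation(times = "numeric", annotations = "data.frame",
                 protocolId = "character"),
  prototype(times = numeric(0), annotations = emptyAnnotations(),
            protocolId = "protocol"))

setValidity("StimulusPattern", function(object) {
  msg <- character(0)
  tt <- object@times
  if (length(tt) && any(tt < 0)) msg <- c(msg, "stimulus times must be >= 0")
  if (length(tt) > 1 && any(diff(tt) <= 0))
    msg <- c(msg, "stimulus times must be strictly increasing")
  ann <- object@annotations
  need <- c("kind", "t0", "t1", "nominal_rate")
  if (!all(need %in% names(ann))) {
    msg <- c(msg, sprintf("annotations must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(ann)) {
    if (!all(ann$kind %in% ANNOTATION_KINDS))
      msg <- c(msg, sprintf("annotation kind must be one of %s",
                            paste(ANNOTATION_KINDS, collapse = ", ")))
    if (any(ann$t0 >= ann$t1))
      msg <- c(msg, "annotation intervals need t0 < t1")
    hi <- if (length(tt)) max(tt) + 10 else 10
    if (any(ann$t0 < 0) || any(ann$t1 > hi + 1e-9))
      msg <- c(msg, "annotations must lie within [0, last stimulus + 10 s]")
    # overlapping annotations of the same kind are ill-formed
    for (k in unique(ann$kind)) {
      a <- ann[ann$kind == k, , drop = FALSE]
      a <- a[order(a$t0), , drop = FALSE]
      if (nrow(a) > 1 && any(a$t0[-1] < a$t1[-nrow(a)] - 1e-12))
        msg <- c(msg, sprintf("overlapping '%s' annotations", k))
    }
  }
  if (length(object@protocolId) != 1)
    msg <- c(msg, "protocolId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusPattern
#'
#' @param times strictly increasing stimulus times (s).
#' @param annotations data.frame of labeled intervals (see
#'   [StimulusPattern-class]); defaults to none.
#' @param protocolId protocol label.
#' @return A [StimulusPattern-class] object.
#' @export
StimulusPattern <- function(times = numeric(0), annotations = emptyAnnotations(),
                            protocolId = "protocol") {
  if (nrow(annotations)) {
    annotations <- annotations[, c("kind", "t0", "t1", "nominal_rate")]
    rownames(annotations) <- NULL
  } else {
    annotations <- emptyAnnotations()
  }
  new("StimulusPattern", times = as.numeric(times), annotations = annotations,
      protocolId = protocolId)
}

#' SpikeTrain: spike times of one trial
#'
#' @slot times strictly increasing spike times (s) within `[tStart, tStop)`.
#' @slot trialId integer trial index (>= 0).
#' @slot tStart,tStop numeric recording window (s).
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", trialId = "integer",
                 tStart = "numeric", tStop = "numeric"),
  prototype(times = numeric(0), trialId = 0L, tStart = 0, tStop = 1))

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  tt <- object@times
  if (length(tt) > 1 && any(diff(tt) <= 0))
    msg <- c(msg, "spike times must be strictly increasing (no duplicates)")
  if (length(tt) && (tt[1] < object@tStart || tt[length(tt)] >= object@tStop))
    msg <- c(msg, "spike times must satisfy tStart <= t < tStop")
  if (object@tStart >= object@tStop) msg <- c(msg, "tStart must be < tStop")
  if (object@trialId < 0) msg <- c(msg, "trialId must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times strictly increasing spike times (s).
#' @param trialId trial index (>= 0).
#' @param tStart,tStop recording window (s); `tStop` defaults to just past the
#'   last spike when omitted.
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(times = numeric(0), trialId = 0L, tStart = 0,
                       tStop = NULL) {
  times <- as.numeric(times)
  if (is.null(tStop))
    tStop <- if (length(times)) max(times) + 1e-6 else tStart + 1
  new("SpikeTrain", times = times, trialId = as.integer(trialId),
      tStart = as.numeric(tStart), tStop = as.numeric(tStop))
}

#' CellRecording: all trials of one cell under one protocol and drug condition
#'
#' The `condition` slot is the set of glutamate receptors blocked at that
#' wash-in stage; the empty set is the drug-free baseline. Cumulative wash-in
#' series are represented by one CellRecording per stage.
#'
#' @slot cellId,protocolId character labels.
#' @slot condition character vector, subset of
#'   `c("mGluR2/3", "AMPAR", "mGluR1", "NMDAR")`.
#' @slot trials list of [SpikeTrain-class]; all trials must share
#'   `tStart`/`tStop` to within 1 ms.
#' @slot stimulus the [StimulusPattern-class] delivered on every trial.
#' @export
setClass("CellRecording",
  representation(cellId = "character", protocolId = "character",
                 condition = "character", trials = "list",
                 stimulus = "StimulusPattern"))

setValidity("CellRecording", function(object) {
  msg <- character(0)
  if (!all(object@condition %in% RECEPTOR_NAMES))
    msg <- c(msg, sprintf("condition must be a subset of {%s}",
                          paste(RECEPTOR_NAMES, collapse = ", ")))
  if (anyDuplicated(object@condition))
    msg <- c(msg, "condition must not repeat receptors")
  if (length(object@trials)) {
    if (!all(vapply(object@trials, is, logical(1), "SpikeTrain")))
      msg <- c(msg, "trials must all be SpikeTrain objects")
    else {
      st <- vapply(object@trials, function(x) x@tStart, numeric(1))
      sp <- vapply(object@trials, function(x) x@tStop, numeric(1))
      if (diff(range(st)) > 1e-3 || diff(range(sp)) > 1e-3)
        msg <- c(msg, "all trials must share tStart/tStop to within 1 ms")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellRecording
#'
#' @param cellId,protocolId labels.
#' @param trials list of [SpikeTrain-class] objects.
#' @param stimulus a [StimulusPattern-class].
#' @param condition character vector of blocked receptors (empty = baseline).
#' @return A [CellRecording-class] object.
#' @export
CellRecording <- function(cellId, trials, stimulus,
                          condition = character(0),
                          protocolId = stimulus@protocolId) {
  new("CellRecording", cellId = cellId, protocolId = protocolId,
      condition = condition, trials = trials, stimulus = stimulus)
}

#' RateTrace: instantaneous firing rate on a uniform time grid
#'
#' @slot t0 time of the first grid point (s).
#' @slot dt grid spacing (s), > 0.
#' @slot values firing rate (spk/s) at `t0 + (seq_along(values) - 1) * dt`;
#'   non-negative and finite.
#' @export
setClass("RateTrace",
  representation(t0 = "numeric", dt = "numeric", values = "numeric"),
  prototype(t0 = 0, dt = 1e-3, values = numeric(0)))

setValidity("RateTrace", function(object) {
  msg <- character(0)
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(object@values)) {
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (any(object@values < -1e-9)) msg <- c(msg, "values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RateTrace
#'
#' @param values firing rates (spk/s) on the grid.
#' @param t0 time of the first sample (s).
#' @param dt grid spacing (s).
#' @return A [RateTrace-class] object.
#' @export
RateTrace <- function(values, t0 = 0, dt = 1e-3) {
  new("RateTrace", t0 = as.numeric(t0), dt = as.numeric(dt),
      values = as.numeric(values))
}

#' ReceptorParams: the three-receptor UBC continuum model
#'
#' Phenomenological generative model of a UBC's firing-rate response to mossy
#' fiber stimulation. The conditional intensity is
#' \deqn{\lambda(t) = \max(0,\; r_0 + a_A x_A(t) + a_1 x_1(t) - a_2 x_2(t))}
#' with an AMPAR component \eqn{x_A} (difference-of-exponentials kernel per
#' stimulus, scaled by a recursively depressing release variable), an mGluR1
#' component \eqn{x_1} (Hill function of an accumulating glutamate signal,
#' low-pass filtered with time constant `tau1`), and an inhibitory mGluR2/3
#' component \eqn{x_2} (unit-peak exponential kernel per stimulus). Receptors
#' listed in `blocked` contribute exactly zero.
#'
#' @slot c continuum coordinate in `[0, 1]`: 0 = fast ON cell, 1 = slow OFF cell.
#' @slot r0 spontaneous drive (spk/s).
#' @slot aA AMPAR weight (spk/s per unit kernel).
#' @slot tauARise,tauADecay AMPAR kernel rise/decay time constants (s),
#'   `tauARise < tauADecay`.
#' @slot uDep per-stimulus depression fraction in `[0, 1]`.
#' @slot tauD depression recovery time constant (s).
#' @slot a1 mGluR1 weight (spk/s).
#' @slot tauG glutamate accumulation decay (s).
#' @slot Kg half-activation of the glutamate Hill function (stimulus units).
#' @slot nHill Hill coefficient (>= 1).
#' @slot tau1 mGluR1 output kernel decay (s).
#' @slot a2 mGluR2/3 weight (spk/s).
#' @slot tau2 mGluR2/3 kernel decay (s).
#' @slot tRef absolute refractory period used when sampling spikes (s).
#' @slot blocked character vector of blocked receptors.
#' @slot rebound logical; add a post-burst AMPAR rebound bump (off by default).
#'
#' @seealso [continuumParams()], [applyBlock()], [responseIntensity()]
#' @export
setClass("ReceptorParams",
  representation(c = "numeric", r0 = "numeric",
                 aA = "numeric", tauARise = "numeric", tauADecay = "numeric",
                 uDep = "numeric", tauD = "numeric",
                 a1 = "numeric", tauG = "numeric", Kg = "numeric",
                 nHill = "numeric", tau1 = "numeric",
                 a2 = "numeric", tau2 = "numeric",
                 tRef = "numeric", blocked = "character", rebound = "logical"),
  prototype(c = 0, r0 = 0, aA = 110, tauARise = 0.01, tauADecay = 0.1,
            uDep = 0.45, tauD = 0.7, a1 = 1000, tauG = 0.2, Kg = 3,
            nHill = 2, tau1 = 0.3, a2 = 0, tau2 = 1, tRef = 0.002,
            blocked = character(0), rebound = FALSE))

setValidity("ReceptorParams", function(object) {
  msg <- character(0)
  taus <- c(tauARise = object@tauARise, tauADecay = object@tauADecay,
            tauD = object@tauD, tauG = object@tauG, tau1 = object@tau1,
            tau2 = object@tau2)
  if (any(taus <= 0)) msg <- c(msg, "all time constants must be > 0")
  if (object@tauARise >= object@tauADecay)
    msg <- c(msg, "tauARise must be < tauADecay")
  if (any(c(object@aA, object@a1, object@a2) < 0))
    msg <- c(msg, "receptor weights must be >= 0")
  if (object@uDep < 0 || object@uDep > 1)
    msg <- c(msg, "uDep must lie in [0, 1]")
  if (object@nHill < 1) msg <- c(msg, "nHill must be >= 1")
  if (object@r0 < 0) msg <- c(msg, "r0 must be >= 0")
  if (object@tRef < 0) msg <- c(msg, "tRef must be >= 0")
  if (!all(object@blocked %in% c("mGluR2/3", "AMPAR", "mGluR1")))
    msg <- c(msg, "blocked must be a subset of {mGluR2/3, AMPAR, mGluR1}")
  if (length(msg)) msg else TRUE
})

#' Construct ReceptorParams directly
#'
#' Most users should start from [continuumParams()]; this constructor is for
#' purpose-built cells (e.g. a pure-AMPAR cell with `a1 = 0, a2 = 0`).
#'
#' @param ... named slot values overriding the class defaults (see
#'   [ReceptorParams-class]).
#' @return A [ReceptorParams-class] object.
#' @export
ReceptorParams <- function(...) new("ReceptorParams", ...)
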