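# Internal numeric helpers shared across modules.

# Linear interpolation of a trace at arbitrary times (rule 2: clamp at ends).
traceAt <- function(trace, t) {
  stats::approx(rateTimes(trace), rateValues(trace), xout = t, rule = 2)$y
}

# Piecewise-linear integral of a trace over [a, b): grid samples inside the
# window plus interpolated endpoint values, trapezoid rule.
traceIntegral <- function(trace, a, b) {
  stopifnot(b > a)
  tt <- rateTimes(trace)
  if (a < tt[1] - 1e-9 || b > tt[length(tt)] + trace@dt + 1e-9)
    stop("integration window [", a, ", ", b, ") exceeds trace extent")
  inside <- tt > a & tt < b
  xs <- c(a, tt[inside], b)
  ys <- c(traceAt(trace, a), rateValues(trace)[inside], traceAt(trace, b))
  pracma::trapz(xs, ys)
}

traceMean <- function(trace, a, b) traceIntegral(trace, a, b) / (b - a)

# First time >= `from` at which the trace reaches (>=) `threshold`, with
# linear interpolation between grid samples. NA when never reached.
firstTimeAtOrAbove <- function(trace, threshold, from) {
  tt <- rateTimes(trace)
  vv <- rateValues(trace)
  keep <- tt >= from - 1e-12
  tt <- tt[keep]; vv <- vv[keep]
  if (!length(tt)) return(NA_real_)
  if (vv[1] >= threshold) return(tt[1])
  i <- which(vv[-1] >= threshold & vv[-length(vv)] < threshold)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  tt[i] + (threshold - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
}

# First time >= `from` at which the trace falls to (<=) `threshold`.
firstTimeAtOrBelow <- function(trace, threshold, from) {
  tt <- rateTimes(trace)
  vv <- rateValues(trace)
  keep <- tt >= from - 1e-12
  tt <- tt[keep]; vv <- vv[keep]
  if (!length(tt)) return(NA_real_)
  if (vv[1] <= threshold) return(tt[1])
  i <- which(vv[-1] <= threshold & vv[-length(vv)] > threshold)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  tt[i] + (threshold - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
}

# Deterministic numeric formatting used by all table writers: parses back to
# the same string on rewrite, and to the value within 1e-9 s for times.
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

# Per-trial RNG substream seed (kept below 2^31).
trialSeed <- function(seed, trial) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(trial)) %% 2147483647)
}
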