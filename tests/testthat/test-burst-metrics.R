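# A synthetic trace builder: piecewise-linear rate on a 1 ms grid over [0, T).
linTrace <- function(breakT, breakV, T = 8, dt = 1e-3) {
  tt <- seq(0, T - dt / 2, by = dt)
  RateTrace(approx(breakT, breakV, xout = tt, rule = 2)$y, t0 = 0, dt = dt)
}

test_that("a triangular bump of base 1.5 s has a 0.75 s half-width", {
  # baseline 20 spk/s; linear rise to 100 at t = 2.75, back to 20 at t = 3.5
  tr <- linTrace(c(0, 2, 2.75, 3.5, 8), c(20, 20, 100, 20, 20))
  m <- burstResponseMetrics(tr, stimOnset = 1.8, stimEnd = 1.99)
  expect_equal(m$baseline_rate, 20, tolerance = 1e-6)
  expect_equal(m$peak_rate, 100, tolerance = 1e-3)
  expect_equal(m$peak_change, 80, tolerance = 1e-3)
  expect_equal(m$half_width, 0.75, tolerance = 2e-3)
  expect_equal(m$pause_duration, 0)
})

test_that("a constant trace has zero peak change and no half-width or pause", {
  tr <- linTrace(c(0, 8), c(20, 20))
  m <- burstResponseMetrics(tr, stimOnset = 2, stimEnd = 2.19)
  expect_equal(m$peak_change, 0, tolerance = 1e-9)
  expect_true(is.na(m$half_width))
  expect_equal(m$pause_duration, 0)
})

test_that("the recovery threshold is half the peak when the peak is below 10 spk/s", {
  # baseline 6; silenced by the end of the burst, then a slow peak of 8
  tr <- linTrace(c(0, 2, 2.1, 2.11, 3, 3.3, 3.6, 8),
                 c(6, 6, 6, 0, 0, 8, 6, 6))
  m <- burstResponseMetrics(tr, stimOnset = 2, stimEnd = 2.19)
  expect_equal(m$peak_rate, 8, tolerance = 1e-2)
  # theta = min(5, 8/2) = 4; rate climbs 0 -> 8 over [3, 3.3], hits 4 at 3.15
  expect_equal(m$pause_duration, 3 + 0.3 * 4 / 8 - 2.19, tolerance = 5e-3)
})

test_that("pause is undefined for cells silent at baseline", {
  tr <- linTrace(c(0, 2, 2.3, 2.6, 8), c(0, 0, 50, 0, 0))
  m <- burstResponseMetrics(tr, stimOnset = 2, stimEnd = 2.19)
  expect_true(is.na(m$pause_duration))
  expect_gt(m$peak_change, 0)
})

test_that("evoked spikes vanish for a trace pinned at baseline", {
  tr <- linTrace(c(0, 8), c(15, 15))
  ev <- evokedSpikeCount(tr, stimOnset = 2, responseStart = 2.1,
                         halfWidth = 0.5, baselineRate = 15)
  expect_equal(as.numeric(ev), 0, tolerance = 1e-9)
})

test_that("a rectangular 30 spk/s excess lasting 1 s yields ~30 evoked spikes", {
  tr <- linTrace(c(0, 2, 2.001, 3, 3.001, 8), c(10, 10, 40, 40, 10, 10))
  # choose the window to cover exactly the rectangle: start 2, 2*hw = 1
  ev <- evokedSpikeCount(tr, stimOnset = 2, responseStart = 2.25,
                         halfWidth = 0.375, baselineRate = 10)
  expect_equal(as.numeric(ev), 30, tolerance = 0.2)
  expect_false(attr(ev, "fallback"))
})

test_that("the evoked count matches a first-principles quadrature", {
  withr::with_seed(61, {
    v <- 20 + cumsum(rnorm(8000, 0, 0.5))
    v <- pmax(v, 0)
  })
  tr <- RateTrace(v, t0 = 0, dt = 1e-3)
  base <- 12
  ev <- evokedSpikeCount(tr, stimOnset = 2, responseStart = 2.2,
                         halfWidth = 0.9, baselineRate = base)
  tt <- rateTimes(tr)
  sel <- tt >= 2 & tt <= 2.2 + 1.8
  want <- oracleTrapz(tt[sel], rateValues(tr)[sel]) - base * (2.2 + 1.8 - 2)
  expect_equal(as.numeric(ev), want, tolerance = 1e-2)
})

test_that("scaling the deviation scales peak change and evoked count, not half-width", {
  base <- 20
  tr1 <- linTrace(c(0, 2, 2.75, 3.5, 8), c(base, base, base + 60, base, base))
  k <- 2.5
  tr2 <- linTrace(c(0, 2, 2.75, 3.5, 8),
                  c(base, base, base + 60 * k, base, base))
  m1 <- burstResponseMetrics(tr1, 1.8, 1.99)
  m2 <- burstResponseMetrics(tr2, 1.8, 1.99)
  expect_equal(m2$peak_change, k * m1$peak_change, tolerance = 1e-3)
  expect_equal(m2$half_width, m1$half_width, tolerance = 5e-3)
  e1 <- evokedSpikeCount(tr1, 1.8, m1$response_start, m1$half_width, base)
  e2 <- evokedSpikeCount(tr2, 1.8, m2$response_start, m2$half_width, base)
  expect_equal(as.numeric(e2), k * as.numeric(e1), tolerance = 0.05)
})

test_that("metrics are equivariant under a rigid time shift", {
  tr1 <- linTrace(c(0, 2, 2.75, 3.5, 8), c(20, 20, 100, 20, 20))
  s <- 1.5
  tr2 <- linTrace(c(0, 2 + s, 2.75 + s, 3.5 + s, 9.5), c(20, 20, 100, 20, 20),
                  T = 9.5)
  m1 <- burstResponseMetrics(tr1, 1.8, 1.99)
  m2 <- burstResponseMetrics(tr2, 1.8 + s, 1.99 + s)
  expect_equal(m2$peak_change, m1$peak_change, tolerance = 1e-6)
  expect_equal(m2$half_width, m1$half_width, tolerance = 2e-3)
  expect_equal(m2$response_start - s, m1$response_start, tolerance = 2e-3)
})

test_that("stronger mGluR2/3 coupling prolongs the pause monotonically", {
  pat <- referenceBurst()
  pauses <- vapply(c(1, 2, 3, 4.5, 6), function(a2) {
    # an OFF-dominated cell (no fast excitation masking the suppression)
    p <- continuumParams(1)
    p@a2 <- a2
    lam <- responseIntensity(p, pat)
    m <- burstResponseMetrics(lam, stimOnset = 1, stimEnd = 1.19)
    m$pause_duration
  }, numeric(1))
  expect_true(all(diff(pauses) >= -1e-9))
  expect_gt(pauses[5], pauses[1])
})

test_that("constant-rate segments average to the underlying waveform", {
  # a rate trace that repeats a fixed 0.2 s motif locked to 5 spk/s stimuli
  dt <- 1e-3
  stim <- seq(0.5, 4.3, by = 0.2)
  tt <- seq(0, 5 - dt / 2, by = dt)
  motif <- function(rel) 10 + 30 * exp(-rel / 0.03) * (rel >= 0)
  phase <- (tt - 0.5) %% 0.2
  vals <- ifelse(tt >= 0.5, motif(phase), 10)
  tr <- RateTrace(vals, t0 = 0, dt = dt)
  out <- constantRateResponse(list(tr, tr), stim, window = 0.2)
  rel <- rateTimes(out$mean_segment)
  expect_equal(rateValues(out$mean_segment), motif(rel), tolerance = 0.05)
  expect_equal(out$peak_rate, 40, tolerance = 0.5)
  expect_equal(out$spikes_per_stimulus,
               oracleTrapz(rel, motif(rel)), tolerance = 0.05)
  expect_error(constantRateResponse(list(tr), stim[1:5], window = 0.2),
               "at least 6")
})
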