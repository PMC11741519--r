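stepGrid <- function(T = 10, dt = 1e-3) seq(0, T - dt / 2, by = dt)

test_that("a constant trace has zero step-evoked spikes during and after", {
  tr <- RateTrace(rep(12, 10000), t0 = 0, dt = 1e-3)
  ch <- stepSpikeChanges(tr, stepOnset = 4, stepOffset = 5)
  expect_equal(ch$spikes_during, 0, tolerance = 1e-9)
  expect_equal(ch$spikes_after, 0, tolerance = 1e-9)
  expect_equal(ch$reference_rate, 12)
})

test_that("a rectangular 20 spk/s excess during the step yields 20 extra spikes", {
  tt <- stepGrid()
  vals <- ifelse(tt >= 4 & tt < 5, 30, 10)
  tr <- RateTrace(vals, t0 = 0, dt = 1e-3)
  ch <- stepSpikeChanges(tr, 4, 5)
  expect_equal(ch$spikes_during, 20, tolerance = 0.1)
  expect_equal(ch$spikes_after, 0, tolerance = 0.1)
})

test_that("an OFF cell loses spikes during a 1 s period of strong input", {
  # 60 stimuli at 60 spk/s from rest: pure suppression of the tonic rate
  lam <- responseIntensity(continuumParams(1), makeBurstPattern(60, 60, t0 = 4))
  ch <- stepSpikeChanges(lam, 4, 5)
  expect_equal(ch$reference_rate, 20, tolerance = 1e-3)
  expect_lt(ch$spikes_during, 0)
  expect_lt(ch$spikes_after, 0)  # the pause outlasts the input
})

test_that("transient excision is an identity when there is nothing to excise", {
  tr <- RateTrace(rep(7, 5000), t0 = 0, dt = 1e-3)
  out <- removeStimulusTransients(tr, numeric(0))
  expect_equal(rateValues(out), rateValues(tr))
  outC <- removeStimulusTransients(tr, c(1, 2, 3), 0.1)
  expect_equal(rateValues(outC), rateValues(tr), tolerance = 1e-12)
})

test_that("excision restores a constant trace carrying stimulus-locked bumps", {
  tt <- stepGrid(T = 5)
  vals <- rep(10, length(tt))
  stims <- c(1, 2, 3)
  for (s in stims) vals[tt >= s & tt < s + 0.05] <- 60
  tr <- RateTrace(vals, t0 = 0, dt = 1e-3)
  out <- removeStimulusTransients(tr, stims, excisionWindow = 0.1)
  expect_equal(rateValues(out), rep(10, length(tt)), tolerance = 1e-6)
})

test_that("excision interpolates linearly across each window on a ramp", {
  tt <- stepGrid(T = 5)
  ramp <- 5 + 2 * tt
  vals <- ramp
  vals[tt >= 2 & tt < 2.08] <- 100  # a bump entirely inside the window
  tr <- RateTrace(vals, t0 = 0, dt = 1e-3)
  out <- removeStimulusTransients(tr, 2, excisionWindow = 0.1)
  # a linear function is reproduced exactly by linear interpolation
  expect_equal(rateValues(out), ramp, tolerance = 1e-9)
})

test_that("excision is idempotent", {
  withr::with_seed(71, v <- pmax(0, 20 + cumsum(rnorm(5000, 0, 0.3))))
  tr <- RateTrace(v, t0 = 0, dt = 1e-3)
  once <- removeStimulusTransients(tr, c(1, 1.05, 2.5), 0.1)
  twice <- removeStimulusTransients(once, c(1, 1.05, 2.5), 0.1)
  expect_equal(rateValues(twice), rateValues(once), tolerance = 1e-12)
})

test_that("the log-normal fit recovers noiseless parameters to 1e-6", {
  tt <- seq(0.001, 3, by = 1e-3)
  A <- 50; mu <- log(0.5); sigma <- 0.5
  clean <- A * exp(-((log(tt) - mu) / sigma)^2)
  tr <- RateTrace(clean, t0 = 0.001, dt = 1e-3)
  f <- fitLognormalPeak(tr, 0, fitWindow = 3)
  expect_true(f$fit_ok)
  expect_equal(f$A, A, tolerance = 1e-6)
  expect_equal(f$mu, mu, tolerance = 1e-6)
  expect_equal(f$sigma, sigma, tolerance = 1e-6)
  expect_equal(f$time_to_peak, 0.5, tolerance = 1e-6)
  expect_lt(f$rss, 1e-8)
})

test_that("the fitted time to peak is robust to additive rate noise", {
  tt <- seq(0.001, 3, by = 1e-3)
  clean <- 50 * exp(-((log(tt) - log(0.5)) / 0.5)^2)
  errs <- vapply(1:100, function(s) {
    withr::with_seed(s, y <- pmax(0, clean + rnorm(length(tt), 0, 2)))
    f <- fitLognormalPeak(RateTrace(y, t0 = 0.001, dt = 1e-3), 0,
                          fitWindow = 3)
    abs(f$time_to_peak - 0.5)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("cells without a significant step response are not fitted", {
  tr <- RateTrace(rep(0, 4000), t0 = 0.001, dt = 1e-3)
  f <- fitLognormalPeak(tr, 0, fitWindow = 3)
  expect_false(f$fit_ok)
  expect_true(is.na(f$time_to_peak))
  small <- RateTrace(rep(3, 4000), t0 = 0.001, dt = 1e-3)
  expect_false(fitLognormalPeak(small, 0, fitWindow = 3)$fit_ok)
})

test_that("an exponential decay halves after tau * ln 2", {
  tau <- 0.8
  tt <- stepGrid(T = 10)
  vals <- ifelse(tt < 2, 40 * exp(0), 40 * exp(-(tt - 2) / tau))
  tr <- RateTrace(vals, t0 = 0, dt = 1e-3)
  hd <- halfDecayTime(tr, peakTime = 2, peakRate = 40, baseline = 0,
                      stepOffset = 2)
  expect_equal(hd, tau * log(2), tolerance = 2e-3)
})

test_that("a never-decaying trace reports a flagged missing half-decay", {
  tr <- RateTrace(rep(40, 5000), t0 = 0, dt = 1e-3)
  hd <- halfDecayTime(tr, peakTime = 1, peakRate = 40, baseline = 0)
  expect_true(is.na(hd))
  expect_true(isTRUE(attr(hd, "no_crossing")))
})

test_that("stronger mGluR2/3 coupling delays the step-response peak", {
  pat <- makeStepProtocol(5, 60, 1, 4)
  steps <- annotations(pat)[annotations(pat)$kind == "step", ]
  on <- steps$t0
  ttps <- vapply(c(0, 2, 4, 6, 8), function(a2) {
    p <- continuumParams(0.6)
    p@a2 <- a2
    lam <- responseIntensity(p, pat)
    ref <- traceMean(lam, on - 1, on)
    fitLognormalPeak(lam, on, baseline = ref)$time_to_peak
  }, numeric(1))
  expect_true(all(diff(ttps) > 0))
})

test_that("a slower mGluR1 kernel prolongs the step-response decay", {
  pat <- makeStepProtocol(5, 60, 1, 4)
  steps <- annotations(pat)[annotations(pat)$kind == "step", ]
  on <- steps$t0; off <- steps$t1
  stim <- stimulusTimes(pat)
  inStep <- stim >= on & stim < off
  hds <- vapply(c(0.3, 0.6, 1.2, 2.4, 4.8), function(t1) {
    p <- continuumParams(0.6)
    p@tau1 <- t1
    lam <- responseIntensity(p, pat)
    exc <- removeStimulusTransients(lam, stim[!inStep], 0.1)
    tt <- rateTimes(exc)
    sel <- tt > on & tt <= off + 3
    pk <- which(sel)[which.max(rateValues(exc)[sel])]
    ref <- traceMean(lam, on - 1, on)
    halfDecayTime(exc, tt[pk], rateValues(exc)[pk], baseline = ref,
                  stepOffset = off)
  }, numeric(1))
  expect_true(all(diff(hds) > 0))
})
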