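test_that("stimulus patterns enforce ordered nonnegative times and sane annotations", {
  expect_error(StimulusPattern(c(0.2, 0.1)), "increasing")
  expect_error(StimulusPattern(c(-0.1, 0.2)), ">= 0|nonneg|negative")
  ann <- data.frame(kind = "burst", t0 = 0.2, t1 = 0.1, nominal_rate = 100)
  expect_error(StimulusPattern(c(0, 0.1), ann))
  over <- data.frame(kind = c("burst", "burst"), t0 = c(0, 0.5),
                     t1 = c(1, 1.5), nominal_rate = c(100, 100))
  expect_error(StimulusPattern(c(0, 0.1), over), "overlap")
})

test_that("spike trains reject out-of-window and non-increasing times", {
  expect_error(SpikeTrain(c(0.2, 0.1), tStart = 0, tStop = 1))
  expect_error(SpikeTrain(c(0.1, 0.1), tStart = 0, tStop = 1))
  expect_error(SpikeTrain(c(0.1, 1.5), tStart = 0, tStop = 1))
  expect_silent(validObject(SpikeTrain(c(0.1, 0.9), tStart = 0, tStop = 1)))
})

test_that("recordings require trials sharing a common time window", {
  a <- SpikeTrain(0.5, trialId = 0L, tStart = 0, tStop = 10)
  b <- SpikeTrain(0.6, trialId = 1L, tStart = 0, tStop = 20)
  expect_error(CellRecording("c1", list(a, b), StimulusPattern()),
               "share|window")
})

test_that("condition labels round-trip between tokens and receptor sets", {
  expect_identical(parseCondition("baseline"), character(0))
  expect_identical(parseCondition("LY"), "mGluR2/3")
  expect_identical(parseCondition("LY+NBQX"), c("mGluR2/3", "AMPAR"))
  expect_identical(parseCondition("LY+NBQX+JNJ"),
                   c("mGluR2/3", "AMPAR", "mGluR1"))
  expect_identical(formatCondition(character(0)), "baseline")
  expect_identical(formatCondition(c("AMPAR", "mGluR2/3")), "LY+NBQX")
  expect_error(parseCondition("XYZ"), "unknown")
})

test_that("a spike table reads back grouped by trial", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,protocol_id,condition,trial,spike_time_s",
               "c1,p1,baseline,0,0.10",
               "c1,p1,baseline,0,0.25",
               "c1,p1,baseline,1,0.11"), path)
  rec <- readRecording(path)
  expect_s4_class(rec, "CellRecording")
  expect_length(trials(rec), 2)
  expect_equal(spikeTimes(trials(rec)[[1]]), c(0.10, 0.25))
  expect_equal(spikeTimes(trials(rec)[[2]]), 0.11)
  expect_identical(cellId(rec), "c1")
})

test_that("declared zero-spike trials survive the round trip", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,protocol_id,condition,trial,spike_time_s",
               "c1,p1,LY,0,",
               "c1,p1,LY,1,0.5"), path)
  rec <- readRecording(path)
  expect_length(trials(rec), 2)
  expect_length(spikeTimes(trials(rec)[[1]]), 0)
  expect_identical(blockedReceptors(rec), "mGluR2/3")
})

test_that("malformed rows and non-monotonic spikes are named errors, not coercions", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,protocol_id,condition,trial,spike_time_s",
               "c1,p1,baseline,0,0.10",
               "c1,p1,baseline,0,abc"), path)
  expect_error(readRecording(path), "line 3")
  writeLines(c("cell_id,protocol_id,condition,trial,spike_time_s",
               "c1,p1,baseline,0,0.30",
               "c1,p1,baseline,0,0.10"), path)
  expect_error(readRecording(path), "non-monotonic")
})

test_that("simulated recordings round-trip through the spike table to 1e-9 s", {
  pat <- referenceBurst()
  lam <- responseIntensity(continuumParams(0.4), pat)
  tr <- sampleTrials(lam, nTrials = 3, seed = 5)
  rec <- CellRecording("simA", tr, pat, condition = c("mGluR2/3", "AMPAR"))
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  back <- readRecording(path, stimulus = pat,
                        tStart = tr[[1]]@tStart, tStop = tr[[1]]@tStop)
  expect_identical(cellId(back), "simA")
  expect_identical(blockedReceptors(back), c("mGluR2/3", "AMPAR"))
  for (i in seq_along(tr))
    expect_equal(spikeTimes(trials(back)[[i]]), spikeTimes(tr[[i]]),
                 tolerance = 1e-9)
})

test_that("step protocols round-trip including the annotation sidecar", {
  sp <- makeStepProtocol(5, c(10, 60), 1, 4)
  path <- tempfile(fileext = ".csv")
  writeStimulusPattern(sp, path)
  back <- readStimulusPattern(path)
  expect_equal(stimulusTimes(back), stimulusTimes(sp), tolerance = 1e-9)
  expect_equal(annotations(back)$kind, annotations(sp)$kind)
  expect_equal(annotations(back)$t0, annotations(sp)$t0, tolerance = 1e-9)
  expect_equal(annotations(back)$nominal_rate, annotations(sp)$nominal_rate)
})

test_that("a 20-stimulus burst table reads as a pattern spanning 0.19 s", {
  pat <- referenceBurst(t0 = 0)
  path <- tempfile(fileext = ".csv")
  writeStimulusPattern(pat, path)
  back <- readStimulusPattern(path)
  expect_length(stimulusTimes(back), 20)
  expect_equal(diff(range(stimulusTimes(back))), 0.19, tolerance = 1e-9)
})

test_that("metrics tables write missing values as empty fields and rewrite byte-identically", {
  df <- data.frame(cell_id = c("a", "b"), peak_change = c(12.5, NA),
                   half_width = c(0.75, NA), pause_duration = c(NA, 1.25),
                   stringsAsFactors = FALSE)
  p1 <- tempfile(fileext = ".csv")
  writeMetricsTable(df, p1)
  txt <- readLines(p1)
  expect_length(txt, 3)
  expect_false(any(grepl("NA|nan", txt)))
  back <- readMetricsTable(p1)
  expect_equal(back$peak_change, df$peak_change)
  expect_true(is.na(back$half_width[2]))
  p2 <- tempfile(fileext = ".csv")
  writeMetricsTable(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
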