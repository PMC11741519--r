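# ubcspike

Quantification of cerebellar **unipolar brush cell (UBC)** spiking responses
to **mossy fiber (MF)** stimulation, plus a phenomenological generative model
of the UBC response continuum for exercising the whole pipeline on synthetic
data.

UBCs are excitatory interneurons of the cerebellar granular layer. A single
MF input can drive strikingly different responses in different UBCs: some
cells fire a brief high-frequency burst immediately after stimulation
(**fast ON**), some build up firing slowly over seconds (**slow ON**), and
some are *suppressed* for one to two seconds before resuming tonic firing
(**OFF**). These phenotypes form a continuum, shaped by the relative
strength of three glutamate-receptor pathways at the single giant MF–UBC
synapse:

* **AMPAR** — fast, depressing excitation (millisecond timescale);
* **mGluR1** — slow excitation activated cooperatively by glutamate
  accumulation during bursts (hundreds of milliseconds to seconds);
* **mGluR2/3** — slow inhibition (an outward current) that delays or
  suppresses firing.

`ubcspike` provides the standard analysis chain for such recordings, and a
three-receptor intensity model that reproduces the continuum so every
analysis step can be validated against known ground truth.

## What the package does

| Stage | Functions |
| --- | --- |
| Data containers & I/O | `SpikeTrain`, `StimulusPattern`, `CellRecording`, `readRecording()`, `writeRecording()`, `readMetricsTable()` |
| Stimulus protocols | `makeBurstPattern()`, `makeStepProtocol()`, `makeInvivoBurstTrain()` |
| Rate estimation | `instantaneousRate()` (reciprocal ISI), `kernelRate()`, `preprocessTrials()` |
| Burst-response metrics | `burstResponseMetrics()`, `evokedSpikeCount()`, `constantRateResponse()`, `analyzeBurstRecording()` |
| Step-response metrics | `stepSpikeChanges()`, `fitLognormalPeak()`, `halfDecayTime()`, `removeStimulusTransients()`, `analyzeStepTrace()` |
| Population & pharmacology | `sortPopulation()`, `normalizeForHeatmap()`, `decomposeComponents()`, `componentPercentage()`, `wilcoxonSignedRank()`, `spearmanCorrelation()` |
| Generative model | `continuumParams()`, `responseIntensity()`, `componentTraces()`, `applyBlock()`, `washInSeries()`, `sampleTrials()`, `simulateCohort()` |

## Worked example

Simulate a slow-ON cell (continuum coordinate `c = 0.75`), record 8 trials
of its response to the reference burst (20 stimuli at 100 spk/s), and run
the full quantification:

```r
library(ubcspike)

pat    <- makeBurstPattern(20, 100, t0 = 1)     # 20 x 100 spk/s at t = 1 s
p      <- continuumParams(0.75)                 # slow-ON model cell
lam    <- responseIntensity(p, pat)             # noiseless intensity (spk/s)
trials <- sampleTrials(lam, nTrials = 8, seed = 42)
rec    <- CellRecording("ubc01", trials, pat)

analyzeBurstRecording(rec, medianWindow = 1001)
#>   cell_id protocol_id condition baseline_rate peak_rate peak_change half_width
#> 1   ubc01 burst20x100  baseline          11.4     70.76       59.36      2.273
#>   pause_duration evoked_spikes response_start
#> 1              0         143.1              1
```

The noiseless intensity of the same cell peaks 107 spk/s above baseline
with a 2.41 s half-width, so 8 near-Poisson trials recover the slow
phenotype (wide half-width, large evoked-spike count) with the expected
shrinkage of the peak from trial averaging.

Decompose the same cell's response into receptor components across the
cumulative antagonist wash-in (mGluR2/3 → AMPAR → mGluR1 blocked):

```r
decomposeComponents(p, pat)
#>   n_baseline   n_ly n_ly_nbqx n_ly_nbqx_jnj mglur23_ratio pct_ampar pct_mglur1
#> 1     280.12 349.07       337             0          1.25      3.46        100
```

Blocking mGluR2/3 *increases* the evoked count (ratio 1.25 > 1, released
inhibition), and essentially the entire remaining long-burst response is
mGluR1-mediated (`pct_mglur1 = 100`), as expected for a slow cell.

A full cohort spanning the continuum:

```r
cohort <- simulateCohort(pat, n = 31, nTrials = 8, seed = 1)
tab    <- burstMetricsTable(cohort$recordings, medianWindow = 1001)
sortPopulation(tab)   # fast-to-slow ordering, pausing cells last
```

Sorting by half-width recovers the programmed continuum ordering with
Spearman rho ≈ 0.95 (seed 1).

## Notes on estimator settings

The reciprocal-ISI estimate is heavy-tailed for near-Poisson spiking. The
default per-trial running median (`medianWindow = 3` samples) only removes
single-sample glitches; for slow, low-rate cells use a window covering many
interspike intervals (e.g. `medianWindow = 1001`, about 1 s on the default
1 ms grid) before measuring half-widths. See the methods vignette
(`vignettes/ubcspike-methods.Rmd`) for the model equations, the generator
constants and their calibration, and known limitations.

## Tests

```r
testthat::test_dir("tests/testthat", package = "ubcspike",
                   load_package = "installed")
```

The suite checks the numerical primitives against independent brute-force
oracles, the metrics against analytically known response shapes, and the
end-to-end pipeline against the generative model's ground truth.
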