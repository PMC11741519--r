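Package: ubcspike
Title: Temporal Transformations of Mossy Fiber Input by Unipolar Brush Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of unipolar brush cell (UBC) spiking responses to
    mossy fiber stimulation in the cerebellar cortex. Provides reciprocal
    interspike-interval instantaneous firing-rate estimation with per-trial
    median filtering, burst-response metrics (baseline-corrected peak, half-width,
    pause duration, evoked spikes), step-response metrics with log-normal
    time-to-peak fitting and transient-excised half-decay times, population
    sorting along the fast-ON to slow-OFF continuum, and glutamate-receptor
    component decomposition across cumulative antagonist wash-in stages
    (mGluR2/3, AMPAR, mGluR1). A phenomenological three-receptor generative
    model simulates the UBC response continuum and the mossy fiber stimulus
    protocols (bursts, rate steps, in-vivo-like burst trains), so the whole
    pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'burst-metrics.R'
    'io.R'
    'pipeline.R'
    'population.R'
    'rate-estimation.R'
    'receptor-model.R'
    'stats-tests.R'
    'step-metrics.R'
    'stimulus-patterns.R'
    'ubcspike-package.R'
    'utils.R'
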