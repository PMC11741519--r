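---
title: "Methods: the UBC response model and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the UBC response model and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubcspike)
```

This vignette documents the generative model behind `continuumParams()` /
`responseIntensity()`, the constants it uses and why, the conventions of the
analysis functions, and the known limitations. It is the reference for every
numeric choice in the package.

## 1. The three-receptor intensity model

A unipolar brush cell's firing is modeled as an inhomogeneous Poisson
process whose intensity is a rectified sum of three receptor-driven
conductance proxies plus a tonic drive:

$$\lambda(t) \;=\; \max\!\bigl(0,\; r_0 \;+\; a_A\,x_A(t) \;+\;
a_1\,x_1(t) \;-\; a_2\,x_2(t)\bigr).$$

Rectification is the *only* nonlinearity applied after summation, so the
contribution of a blocked receptor is exactly zero and component
decompositions are exact wherever the rate is positive (see
`componentTraces()`).

**AMPAR (fast excitation, depressing).** Each stimulus $k$ at time $t_k$
adds a unit-peak difference-of-exponentials kernel scaled by a short-term
depression factor $D_k$:

$$x_A(t) = \sum_k D_k\,\alpha(t - t_k), \qquad
\alpha(s) \propto e^{-s/\tau_{A,\mathrm{decay}}} - e^{-s/\tau_{A,\mathrm{rise}}},$$

with $\tau_{A,\mathrm{rise}} = 10$ ms, $\tau_{A,\mathrm{decay}} = 100$ ms,
and release recovering between stimuli as

$$D_1 = 1, \qquad
D_{k+1} = 1 - \bigl(1 - D_k(1 - u)\bigr)\,e^{-\Delta t_k/\tau_D},$$

with release fraction $u = 0.45$ and recovery constant $\tau_D = 0.7$ s.

**mGluR1 (slow excitation, cooperative).** A glutamate accumulation
variable $g(t)$ gains $+1$ per stimulus and decays with $\tau_g = 0.2$ s.
Cooperative activation is a Hill function
$h(t) = g^2/(g^2 + K_g^2)$ with $K_g = 3$ and Hill coefficient 2, so a
single stimulus ($g \le 1$) produces almost no activation while bursts
engage the pathway strongly. The activation is low-pass filtered by a
unit-peak exponential kernel with time constant $\tau_1$, which is the main
axis of slow-cell diversity.

**mGluR2/3 (slow inhibition).** Each stimulus adds a unit-peak exponential
with $\tau_2 = 1$ s; the summed variable $x_2$ enters with a negative sign,
producing the post-burst pause of OFF-dominated cells.

Spikes are drawn from $\lambda(t)$ by thinning with an absolute refractory
period $t_\mathrm{ref} = 2$ ms (`sampleTrials()`), with an independent,
reproducible substream per trial.

## 2. The fast-to-slow continuum

`continuumParams(c)` maps a single coordinate $c \in [0, 1]$
(0 = fast ON, 1 = OFF) to receptor weights:

| Parameter | Mapping | At $c=0$ | At $c=1$ |
| --- | --- | --- | --- |
| AMPAR weight $a_A$ | $A_{\max}(1 - c)$ | 110 | 0 |
| mGluR1 weight $a_1$ | $M1_{\max}(1 - c^2)$ | 1000 | 0 |
| mGluR2/3 weight $a_2$ | $G2_{\max}\,c$ | 0 | 6 |
| tonic drive $r_0$ | $R_{\max}\,c$ | 0 | 20 spk/s |
| mGluR1 kernel $\tau_1$ | $0.3 \cdot (4/0.3)^{c}$ (geometric) | 0.3 s | 4 s |

The concave $1 - c^2$ mapping for $a_1$ keeps the slow excitatory pathway
strong through the middle of the continuum (where real slow-ON cells live)
while still vanishing at the OFF extreme; a linear mapping starves
mid-continuum cells of slow excitation relative to the growing mGluR2/3
inhibition.

### Calibration of the constants

$A_{\max} = 110$, $M1_{\max} = 1000$, $G2_{\max} = 6$ and
$R_{\max} = 20$ are tunable generator constants, chosen (before the test
suite was frozen) so that the simulated continuum reproduces the
qualitative phenotypes:

* fast cells ($c \le 0.2$) peak above 100 spk/s on 1–2 stimulus bursts and
  respond roughly equally (within 3×) across burst lengths;
* slow cells ($c \ge 0.6$) show peak responses growing monotonically with
  burst length (1, 2, 5, 10, 20 stimuli) and half-widths increasing from
  ≈ 0.8 s to ≈ 4.5 s along the continuum;
* the OFF extreme ($c = 1$) shows no excitatory peak and a ≈ 2 s pause
  after the 20 × 100 spk/s burst.

All kinetic constants ($\tau$'s, $u$, $K_g$, Hill coefficient) are kept at
their physiologically motivated defaults above; only the four amplitude
constants were calibrated.

## 3. Stimulus protocols

* `makeBurstPattern(n, rate)` — bursts of 1–20 stimuli at e.g. 100 spk/s;
  the reference categorization protocol is 20 × 100 spk/s.
* `makeStepProtocol(baselineRate, stepRates, stepDuration, interval)` — a
  regular low-rate baseline train (e.g. 5 spk/s) with 1 s steps to
  10–60 spk/s at 4 s onset-to-onset intervals, mimicking smooth-pursuit MF
  rate modulation.
* `makeInvivoBurstTrain(duration, ...)` — a renewal process of short
  high-frequency bursts (2–23 stimuli at 300 spk/s), with dead time plus an
  exponential gap calibrated so the expected burst count equals
  `duration * burstRate`.

## 4. Analysis conventions

**Rate estimation.** `instantaneousRate()` is the reciprocal of the
interspike interval containing each grid point (1 ms grid), zero outside
the recorded ISIs. `preprocessTrials()` median-filters each trial's trace
and averages across trials.

*The median window matters.* For near-Poisson spiking the reciprocal ISI
is heavy-tailed (the ISI density is positive at zero), so a 3-sample
median only removes glitches. Slow, low-rate cells need a window spanning
many ISIs — around 1 s (`medianWindow = 1001`) — before half-widths are
measurable; with the short default, noise spikes truncate slow cells'
half-widths and can even invert the continuum ordering. The package leaves
the default conservative (3) and the cohort-level examples pass the wider
window explicitly. A Gaussian `kernelRate()` estimator is provided as an
alternative; in our checks it recovered the continuum slightly *less*
reliably than the wide median at comparable smoothing.

**Burst metrics** (`burstResponseMetrics()`): baseline is the mean rate
over the 1 s before stimulus onset; the peak is searched after the last
stimulus (optionally including the stimulation period). The half-width is
the full width at half maximum of the *peak-containing lobe* — the last
up-crossing of the half level before the peak and the first down-crossing
after it — which is robust when an early fast transient precedes a slow
main response. The pause is the time from the last stimulus until the rate
first reaches $\min(5, \mathrm{peak}/2)$ spk/s; it is 0 if the rate never
drops below that threshold and undefined (NA) for cells silent at baseline.
`evokedSpikeCount()` integrates the baseline-corrected rate from stimulus
onset to two half-widths after response onset (trapezoid rule), with a
flagged 2 s fallback window when the half-width is undefined.

**Step metrics**: spike-count changes during and for 3 s after each step
relative to the preceding 1 s; a log-normal fit
$A \exp\{-[(\ln t - \mu)/\sigma]^2\}$ of the baseline-subtracted rate gives
the time to peak $e^{\mu}$ (multi-start Levenberg–Marquardt;
`fitLognormalPeak()`); the half-decay time is measured on a trace with
single-stimulus transients excised by linear interpolation
(`removeStimulusTransients()`), so responses to individual baseline stimuli
are not mistaken for slow decay.

**Population**: `sortPopulation()` orders cells with
`peak_change > 8` spk/s by ascending half-width (fast → slow), the rest by
ascending pause duration; missing keys sort last and are flagged.
`decomposeComponents()` quantifies the evoked-spike count at each stage of
the cumulative wash-in (mGluR2/3 → AMPAR → mGluR1 blocked) and reports
each receptor's percentage of the immediately preceding stage, excluding
stages with fewer than 5 spikes.

## 5. Limitations

* Spiking is Poisson (with refractoriness). Real UBCs fire much more
  regularly, so simulated single-trial rate traces are substantially
  noisier than cell-attached recordings; this is why cohort-level analyses
  need the wide median window.
* NMDAR currents and spillover dynamics are not modeled; the AMPAR kernel
  subsumes all fast excitation, and the slow "rebound" AMPAR component is
  off by default.
* The intensity model is phenomenological: receptor variables are kernel
  sums, not biophysical conductances, and the linear-plus-rectification
  interaction ignores driving-force and spike-threshold nonlinearities.
* The continuum parameterization is one-dimensional by construction; real
  populations scatter around it.

## 6. Session info

```{r}
sessionInfo()
```
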