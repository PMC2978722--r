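# nirsdecode

Speeded behavioral-state decoding for functional near-infrared spectroscopy
(fNIRS) time series.

## The problem

fNIRS measures cortical oxy- and deoxy-hemoglobin concentration changes at
~10 Hz. Because the hemodynamic response peaks roughly 6 s after the
underlying neural activity, a brain-computer interface or neurofeedback
system driven by signal amplitude alone reacts seconds late. `nirsdecode`
is for researchers building such real-time systems: it classifies **every
sample** of a recording as task or rest with a linear support vector
machine, and reduces the detection latency by enriching the per-sample
feature vector with recent signal history, gradients, both chromophores,
and CNR-ranked multi-channel spatial patterns.

## Method at a glance

1. **Causal detrending** — each channel is filtered with the difference of
   two exponential moving averages, `g(t) = S(t) − L(t)`, with spans
   `α_S = 20` and `α_L = 100` samples (2 s / 10 s at 10 Hz) and
   `M(t) = λ x(t) + (1−λ) M(t−1)`, an O(1)-per-sample online band-pass.
2. **Feature spaces** — for history length `y` samples, each channel and
   signal contributes lags `0..y` (`y+1` columns; both chromophores give
   `2(y+1)`). Representations: amplitude, first/second-order gradient
   (amplitude at lag 0 retained); chromophore combinations: oxy, deoxy,
   both, total (sum), CBSI-corrected oxy
   (`(oxy − α·deoxy)/2`, `α = sd(oxy)/sd(deoxy)`).
3. **Channel ranking** — contrast-to-noise ratio
   `CNR = (mean_task − mean_rest) / s_pooled`, task window 6–12 s after
   block onset, rest window −5–0 s, computed on training trials only.
4. **Decoding** — linear soft-margin SVM (`C = 128`, libsvm backend),
   trained on the first half of trials, tested on the second; per-sample
   labels ±1 from the behavioral block schedule.
5. **Evaluation** — per-timepoint accuracy plus per-trial **onset delay**
   (block onset → first task-classified sample) and **offset delay**
   (block offset → first rest-classified sample), censored when no
   detection occurs before the next block.

A block-design simulator (`simulationSpec()` / `generateRecording()`)
produces recordings with known per-channel activation amplitudes, a
~6 s-peaking double-gamma response, anti-correlated deoxy, slow drift and
instrument noise, so the whole pipeline runs and is tested without human
data.

## Worked example

```r
library(nirsdecode)

sim <- generateRecording(simulationSpec(nChannels = 8, nTrials = 10, seed = 1001))
sim$recording
#> NirsRecording: 3200 samples x 8 channels @ 10 Hz (320.0 s)
#>   channels: ch01, ch02, ch03, ch04, ch05, ch06 ...

res <- decodeRecording(sim$recording, sim$events,
                       FeatureSpec("ch01", historySec = 1))
res$accuracy
#> [1] 0.7693333
res$delays
#> DelayResult (5 trials): onset 1.78 s (se 0.55, 0 censored), offset 0.94 s (se 0.25, 0 censored)

runFullPipeline(sim$recording, sim$events, maxChannels = 8)
#>      condition accuracy onsetDelay offsetDelay onsetCensored offsetCensored nChannels
#> 1     baseline    0.671       5.38        4.20             0              0         1
#> 2      history    0.741       1.74        1.70             0              0         1
#> 3 historyDeoxy    0.743       1.82        0.74             0              0         1
#> 4         full    0.757       1.76        1.22             0              0         2
```

Reading the table: the one-dimensional `baseline` classifier (a pure
amplitude threshold on the top-CNR channel) detects task onsets 5.4 s late
— it is locked to the hemodynamic rise. Adding 1 s of signal history
(`history`) cuts the onset delay to under 2 s and raises accuracy by 7
points; adding deoxy-Hb and extra CNR-ranked channels buys a further
accuracy increment. `sweepHistory()`, `sweepSignals()` and
`sweepChannels()` expose the individual axes; `runCohort()` aggregates a
multi-recording comparison.

A command-line interface wrapping the same functions (subcommands
`simulate`, `preprocess`, `rank`, `features`, `classify`, `sweep`,
`report`) is installed at
`system.file("cli", "nirsdecode.R", package = "nirsdecode")`.

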