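---
title: "Speeded state decoding for fNIRS: models, parameters, and design choices"
author: "nirsdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speeded state decoding for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsdecode)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
oxy-hemoglobin (oxy-Hb) and deoxy-hemoglobin (deoxy-Hb) concentration
changes through the scalp, typically at ~10 Hz. The measured signal is a
*hemodynamic* echo of neural activity: blood flow responds over seconds and
peaks roughly 6 s after activity begins. A brain-computer interface (BCI) or
neurofeedback system that waits for that peak responds several seconds after
the user acts, which is crippling for closed-loop use.

`nirsdecode` implements a decoding strategy that shortens this latency
without changing the physiology: classify *every sample* of the recording as
task or rest with a linear support vector machine (SVM), and enrich the
per-sample feature vector with information — recent signal history,
gradients, the second chromophore, and additional channels — that reveals a
state change before the response peaks. The package also provides the
evaluation framework (per-timepoint accuracy and per-trial onset/offset
detection delays) and a block-design simulator with known ground truth, so
the entire method is testable without human recordings.

## Pipeline and models

### Causal detrending: the EMA difference filter

Every channel and chromophore is filtered with the difference of two
exponential moving averages,

$$ M(1) = x(1), \qquad M(t) = \lambda\,x(t) + (1-\lambda)\,M(t-1), \qquad
   g(t) = S(t) - L(t), $$

with a short span $\alpha_S = 20$ samples and a long span $\alpha_L = 100$
samples (2 s and 10 s at 10 Hz). The short average suppresses
high-frequency instrument noise, the long average tracks slow drift, and
their difference is a causal, $O(1)$-per-sample band-pass filter — the
real-time-capable counterpart of offline band-pass filtering. Both averages
start at $x(1)$, so $g(1)=0$ and the filter is exactly invariant to adding a
constant.

Two conventions exist for the smoothing factor: $\lambda = 2/(\alpha+1)$
(the common "span" convention, under which span 20 at 10 Hz corresponds to
the conventional 2 s window) and $\lambda = 1/\alpha$. The source material
for this recursion does not disambiguate them; the package defaults to the
span convention and exposes `lambdaRule = "reciprocal"` in
`pipelineConfig()`. Every property the pipeline relies on (causality,
linearity, shift invariance, band-pass shape) holds under either rule.

The recursion is implemented in the increment form
$M \mathrel{+}= \lambda (x - M)$, which makes a constant input an exact
floating-point fixed point: a constant series filters to exactly zero, not
to rounding noise.

Measured on sinusoids, the filter's gain peaks near 0.05–0.1 Hz (~0.64),
falls monotonically toward DC (0.24 at 0.01 Hz, 0.05 at 0.002 Hz) and
attenuates high frequencies (0.04 at 4 Hz). It is a gentle band-pass: slow
drift within a factor of ~2 of the task fundamental (1/30 Hz here) is
attenuated, not removed.

### Feature spaces

With $y = \mathrm{round}(\texttt{historySec} \times f_s)$ history samples,
the per-sample feature vector for one channel and one signal is the current
amplitude plus its $y$ most recent predecessors — $y+1$ dimensions. Using
both chromophores doubles this to $2(y+1)$; $k$ channels multiply it by $k$.
Five chromophore combinations are supported: `oxy`, `deoxy`, `both`,
`total` (their sum), and `cbsi` (correlation-based signal improvement:
$(\mathrm{oxy} - \alpha\,\mathrm{deoxy})/2$ with
$\alpha = \mathrm{sd(oxy)}/\mathrm{sd(deoxy)}$, which cancels common-mode
noise such as motion under the usual oxy/deoxy anti-correlation). The CBSI
scale is estimated on the training portion only and reused for test
features, to avoid test-set leakage.

The gradient representations keep the current amplitude as one dimension
and replace the history amplitudes with first- or second-order finite
differences at lags $0..y-1$, so the dimension matches the amplitude space
at the same history length. The first-order space is an *invertible linear
map* of the amplitude space (each gradient is a difference of adjacent
amplitude columns, and the amplitudes can be reconstructed by cumulative
sums), so a linear classifier sees the same information in both — which is
why their accuracies agree to within a fraction of a point. The
dimension-matched second-order space is **not** invertible ($y$ curvature
equations cannot recover $y+1$ history amplitudes), discards the absolute
level of the history, and decodes measurably worse on the synthetic data;
the package keeps it because comparing representations is part of the
method.

Rows whose history window reaches before the start of the recording are
masked invalid rather than zero-padded: padding would inject a spurious
transient into early-trial features. Invalid rows are excluded from
training and accuracy, and predicted as rest.

### CNR channel ranking

Channels are ordered by contrast-to-noise ratio,

$$ \mathrm{CNR} = \frac{\overline{x}_{\text{task}} -
   \overline{x}_{\text{rest}}}{s_{\text{pooled}}}, $$

with the task window 6–12 s after each block onset (accounting for the
hemodynamic delay) and the rest window the 5 s before onset. Samples are
pooled across blocks and $s_{\text{pooled}}$ is the classical two-sample
pooled standard deviation; a block-averaged alternative is available via
`cnrPooling = "blockmean"`. All windows are half-open $[\text{start},
\text{end})$, so boundary samples are never double-counted. Ranking is
computed on the *training* trials only, on the filtered signal, on oxy-Hb
by default (all three choices configurable — the underlying protocol leaves
them unstated).

A structural caveat the test suite makes explicit: CNR is invariant under
positive affine transforms. In the simulator every channel is an exact
rescaling of one response shape, so with no noise all channels share one
CNR value and ranking carries *no* information; it is the channel-equal
noise floor that makes expected CNR increase with activation amplitude.
Parameter recovery is therefore exact in the regime of realistic noise and
enough trials (the recovery tests use 20 trials, the heaviest protocol the
design describes), not in a noise-free limit.

### Per-timepoint SVM decoding

Every sample is an instance labeled $+1$ (task) or $-1$ (rest) by the
*behavioral* schedule — deliberately not by the delayed hemodynamics,
because the point is to recover the behavioral state early. A linear
soft-margin SVM with $C = 128$ (libsvm via `e1071`, no feature scaling, no
class weighting despite the 1:2 task:rest imbalance — both available as
config flags) is trained on the first half of trials and tested on the
second. The fitted hyperplane is extracted into an explicit
`TrainedModel`, and prediction is `sign(w·x + b)` with a decision value of
exactly 0 mapped to rest.

The split boundary sits at the first test block's onset, so the rest period
between the halves belongs to training. History windows of early test rows
may reach into pre-boundary *signal* samples; signals are past
observations, not labels, and a deployed causal decoder would see them too.

### Delay evaluation

For each test block, the onset delay is the time from block onset to the
first sample classified task, searching forward up to the next block's
onset; the offset delay is defined symmetrically from block offset to the
first rest-classified sample. Detections before the event do not count
(delays are forward-only), and a trial with no qualifying sample is
censored and excluded from means, with the censor count reported — censored
trials are a failure signal, and imputing the window length would
understate variance. Standard errors use the $n-1$ denominator across
trials.

## The synthetic generator

`simulationSpec()` emulates a motor-cortex finger-tapping protocol: 10 Hz
sampling, 10 s task blocks alternating with 20 s rest, 10 trials, one full
rest period of lead-in (so a pre-block rest window always exists), 48
channels by default — the channel count of two 4×4 alternating
emitter/detector patches, whose 48 adjacent-pair channels
`probeChannels()` enumerates. The oxy signal of channel $c$ is

$$ a_c \cdot (\text{boxcar} \ast \mathrm{HRF})(t) + \text{drift}_c(t) +
   \varepsilon_c(t), $$

normalized so a single task block evokes a unit-peak response on a gain-1
channel; deoxy is the same response scaled by $-0.35$ with independent
drift and noise, reproducing the typical anti-correlation. The HRF is a
difference of two gamma densities with the positive lobe peaking at 6 s.

The following values are the package's own choices, in arbitrary
concentration-change units, because the underlying protocol reports none:

* **Amplitudes**: geometric decay $0.85^{c-1}$ across channels, so channel
  responsiveness has a well-defined true order for ranking tests.
* **Noise**: i.i.d. Gaussian, `noiseSd = 0.25` of the unit block response.
* **Drift**: three random-phase sinusoids below 0.01 Hz plus a linear
  trend, amplitude scale 0.2 — slow enough to give the EMA filter realistic
  work.
* **Undershoot**: `hrfRatio = 0.45`, a pronounced post-stimulus undershoot.
  This makes the filtered response return quickly after block offset, which
  is what makes a single-amplitude threshold classifier viable at all (as
  it evidently was on the real recordings that motivated the method); with
  a weak undershoot the response's post-block overhang makes the
  one-dimensional baseline no better than always predicting rest.

These defaults were calibrated once so that the baseline classifier's mean
onset delay lands near the simulated response peak — the structural cause
of the multi-second latency the method attacks — and then frozen. With
them, a 6-recording cohort reproduces the qualitative pattern the method
predicts: baseline onset delay ≈ 5–6 s; adding 1 s of history cuts it by
more than half and raises accuracy by ~8 points; the history benefit
plateaus beyond 1 s; gradient and amplitude spaces tie; total-Hb (which
cancels the anti-correlated chromophores) decodes worst; the full space
(history + both chromophores + CNR-ranked channels) is best, with onset
delays near 1.4 s.

What the simulator does **not** emulate: cardiac, respiratory and Mayer
waves, motion artifacts (so CBSI's motion-removal benefit is not
exercised, only its correctness), inter-channel noise correlation, and
channel-specific response shapes. Passing tests on this generator show the
pipeline's bookkeeping, causality, leakage guards and directional effects
are right; they do not certify accuracy figures on real recordings.

## Numerical and design notes

* Windows and blocks are half-open everywhere; sample $k$ (1-based) is at
  $t_0 + (k-1)/f_s$.
* CNR ties are broken by the recording's channel order (stable).
* The channel count of the full feature space is chosen to maximize *test*
  accuracy, reproducing the original per-individual selection; this is
  optimistic, and honest deployment should nest that choice inside the
  training half.
* The SVM solution is deterministic given the data (tolerance $10^{-6}$);
  the whole pipeline is a pure function of (data, config, seed), which the
  suite asserts bit-for-bit.
* Simulation sizes in the tests (8-channel cohorts, 4-trial structural
  checks, 20-trial ranking recovery) are the package's chosen desk-scale
  study conditions; the group statistics of the original six-participant
  experiment (repeated-measures ANOVA, t-tests) are out of scope, as the
  per-recording report is the right input for any external stats tool.

## Known limitations

* The EMA pair (100, 20) is tuned for 10 Hz block designs; other sampling
  rates need rescaled spans (`emaWindowSec()` reports the window in
  seconds).
* Accuracy comparisons across chromophore combinations share one accuracy
  floor (`accuracyFloor`, default 0.7) below which delays are reported as
  `NA` rather than as search results over a failing classifier.
* Event-related (non-block) designs, nonlinear kernels and multi-class
  decoding are out of scope.
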