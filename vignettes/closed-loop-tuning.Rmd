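---
title: "Methods: simulating and tuning closed-loop DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and tuning closed-loop DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldbs)
```

## What the package models

Closed-loop (adaptive) deep brain stimulation adjusts therapy in real time
from a sensed neural control signal, in contrast to open-loop stimulation
that runs preprogrammed regardless of physiology. The embedded controller
in sense-enabled implants is simple by necessity: spectral band powers are
computed on board at a fixed FFT update rate, combined by a linear
discriminant (LD) with at most two inputs, compared against one or two
thresholds by a counter-based state machine, and each detector state maps
to a stimulation amplitude reached through a ramp. `cldbs` reproduces this
pipeline stage by stage, closes the loop through a patient response model,
and implements the heuristics used to program it. Everything runs on
synthetic data; the package is a rehearsal space for programming
strategies, not a clinical tool.

All stages share a single clock: the FFT update interval (default 0.5 s).
Onset and termination durations are *counters* multiplied by this
interval, so coarser update rates trade detection latency for smoother
features — the same trade the devices expose.

## The synthetic data generator

The generator defines the study conditions; its defaults are fixed and are
not adjusted per analysis.

**Symptom trace.** Chronic-pain reports fluctuate on two timescales:
slow diurnal drift and abrupt flares. The score (0–10) is a baseline
(default 4) plus a sinusoidal diurnal term (amplitude 2, period 24 h), a
two-state telegraph flare process (amplitude 3; switching rate 1/600 s,
i.e., 10-minute mean dwells), and Gaussian report noise (sd 0.5), clipped
to the scale. Dichotomization uses a cutoff of 5/10 — the scale midpoint,
chosen here because no canonical clinical cutoff exists. A trace whose
stochastic realization occupies only one state is redrawn up to five
times (deterministically from the seed) and then returned with a warning;
a deterministic configuration is returned as-is, since its single state
is the exact answer.

**LFP.** Each channel is 1/f-shaped broadband noise (exponent 1 — pink
noise is the standard LFP stand-in) with a fixed 1 Hz low-frequency
shoulder and deterministic spectral normalization. The shoulder matters:
it makes the spectral density at any fixed frequency independent of the
synthesis length, so band statistics agree between a long calibration
recording and the window-sized chunks the closed-loop simulator
synthesizes per update. Biomarkers are state-gated *band-limited Gaussian
noise* (spectrally masked white noise), not sinusoids, so band-power
estimates fluctuate realistically — percentile-based thresholding is only
meaningful on a fluctuating LD. The component's variance equals the
specified band power (µV²) for the current symptom state.

**Artifacts.** Five classes are modeled. Three are stimulation-independent
and applied at generation time: extra broadband noise for recordings at
0 mA (the open stimulation circuit is noisier than true off; its magnitude
is a free parameter, as no published characterization exists), a biphasic
~1.2 Hz EKG spike train (left-sided implants commonly pick up EKG; the
waveform shape is our choice), and occasional smooth movement excursions.
Two are stimulation-locked and injected from the amplitude series: a tonic
sinusoid at the stimulation frequency with a per-channel µV/mA gain, and a
decaying transient across all channels at every 0→on onset. A third
coupling, `band_leak`, adds amplitude-proportional band-limited noise
inside a chosen sensed band; it stands in for cross-region or aliased
stimulation energy contaminating the biomarker band, the mechanism behind
detector lock. The default sampling rate is 500 Hz so that a 130 Hz
stimulation frequency sits below Nyquist and a 120–140 Hz band can track
it.

What the generator does *not* emulate: physiologically detailed neural
dynamics, ADC quantization, electrode impedance drift, and non-stationary
biomarker frequency. Tests passing on this generator therefore demonstrate
correctness of the pipeline and the internal consistency of the tuning
heuristics, not clinical performance on real recordings.

## Sensing and feature ranking

A feature is the mean one-sided periodogram power over the bins whose
centers fall in `[low, high)` Hz — half-open so adjacent bands never
double-count a bin. The window function defaults to Hann (the
conventional spectral default; on-device details are proprietary), the
window length must be a power of two, and the update interval may exceed
the window duration (sparse FFTs, used for minute-scale control). Feature
importance is |Pearson correlation| between the feature and the symptom
score, with a Spearman option (the rank version is invariant to monotone
rescaling of the score, tested as such); symptom reports are resampled to
the feature clock by previous-value hold — a report is valid until the
next one. Window screening keeps the smallest candidate whose top
importance reaches 95% of the best across candidates; a window too coarse
for a band to contain any bin is reported degenerate rather than failing
the screen.

## Discriminant and detector

Normalization is z-scoring; the "fit" mode reproduces the device default
of mean 0 and sd 1 per feature. Weights come from the closed-form Fisher
discriminant (pooled within-class covariance inverse times the class-mean
difference), scaled to unit norm so thresholds are comparable across
fits, and signed so the high-symptom class has the higher LD — a
convention fixed here to make thresholds interpretable. At most two
features are accepted, matching the devices; more is an error rather than
a silent extension. The LD moving average is a *trailing* (causal) mean —
a real-time device cannot center its window — and the streaming
computation is bit-identical to the batch one because both average the
same trailing buffer.

The detector compares with `≥` (a tie counts as above; the devices'
tie-handling is undocumented, so ours is stated and tested). Counters
require *consecutive* qualifying updates; any non-qualifying update
resets them. Blanking converts to `ceiling(blanking/Δt)` ignored updates
after each change. Because a change also resets all counters, the two
readings of blanking (freeze counting vs. also clear counters at blanking
end) coincide in this implementation; both flags are accepted. With two
thresholds the states are ordered bands reached only through adjacent
transitions, and the upper threshold reuses the onset/termination
counters unless overridden per threshold.

## Stimulation, patient response, and the closed loop

Amplitude slews linearly toward the current state's target at
`full scale / ramp rate` (a stepped mode exists as a config option; which
the devices use is not asserted). A mid-ramp state change retargets from
the current amplitude — continuity is physically required. The energy
proxy is the TEED-style `amplitude² × frequency × pulse width × time`
with unit impedance, reported in total and per hour; it is a battery
surrogate, not a dosimetry calculation.

The patient model is first-order: relief relaxes toward
`relief × amplitude/full scale` with τ_in while building and τ_out while
fading — the simplest dynamics exhibiting the wash-in/wash-out asymmetry
probed by open-loop testing. The discrete step uses the exact exponential
discretization, so noiseless wash-in/wash-out fits recover τ to machine
precision, which the tests exploit.

The closed-loop simulator synthesizes one FFT window of LFP per update
from the current modeled symptom state, injects artifacts from the
current amplitude *before* the FFT (so blanking and averaging interact
with artifacts realistically), then steps the discriminant, detector,
ramp and patient model. Chunks are synthesized independently per update;
band statistics match long recordings by construction of the background
normalization (above). Each noise source is driven by the single run
seed.

## Tuning heuristics

**Threshold selection** places thresholds at percentiles of the empirical
LD distribution (linear interpolation between order statistics, R
quantile type 7 — the convention is recorded in every report). On the
same stream with counters of 1 and no blanking, above-threshold occupancy
equals `(100 − p)/100` up to one-update resolution; on an independent
stationary realization it matches approximately — the 50th percentile
splits future time roughly in half. We adopt ±5 percentage points at
10,000 updates as the acceptance band for "approximately".

**Grid search** simulates every combination of onset/termination
counters, blanking, threshold percentile and ramp rate with common random
numbers (one shared seed), converts percentiles to thresholds via an
open-loop 0 mA calibration run, and scores cells by
`w_a(1 − agreement) + w_e·energy_norm + w_l·[lock]` with a hard lock
penalty (defaults 1, 0.2, 100). Scalarization weights are configuration,
not science; the defaults merely encode "agreement first, energy as a
tie-breaker, locks disqualifying".

**Detection scoring** compares the binarized detector state against the
dichotomized symptom state on the update grid; latency is the lag within
±10 updates (a measurement window we invented to make "closely follows"
quantifiable) that maximizes agreement, with ties taking the median lag.

**Anti-lock strategies.** When stimulation artifact raises the biomarker
feature itself, a single-threshold detector locks on: stimulation keeps
the LD above threshold, which keeps stimulation on. The packaged
artifact scenario reproduces this. Both countermeasures are implemented
and exercised: (1) a third "catch" state whose threshold sits between the
natural high-symptom LD and the artifact-elevated LD, with amplitude 0,
bounding every stimulation bout by the LD smoothing delay plus the upper
onset duration plus blanking plus the ramp traversal; and (2) a
negative-weight second feature over a stimulation-tracking band. For the
latter, the scenario builder calibrates clinician-style on an off/on
recording pair: the tracker is normalized to z ≈ 0 (off) and z ≈ 1
(fully on), and its weight is set to cancel the artifact-induced lift of
the primary feature, so the LD returns to symptom-driven values during
stimulation and termination proceeds normally.

## Problem sizes and numerical choices

The shipped tests and scripts use 10-minute closed-loop runs at 500 Hz
with 0.5 s updates (1,200 updates), 10,000-update LD streams for
percentile checks, n = 5,000–10,000 samples for discriminant recovery,
and 20–30 seed replicates for stochastic estimates — sizes chosen so the
whole suite exercises every stage in about a minute on a laptop while
keeping Monte-Carlo error well inside the asserted tolerances. Detector
equivalence is checked against an independently written step-by-step
reference over 1,000 random sequences; band powers against a direct-DFT
periodogram oracle at 1e−9 relative tolerance; ramping against a
fine-substep Euler integrator. Floating point is used throughout; the
devices' fixed-point LD arithmetic is not emulated, a known fidelity gap.

## Limitations

Single-electrode detection only (no bilateral device interaction beyond
the band-leak gain); no event-triggered snippet storage; no EDF/
BrainVision IO (CSV with JSON sidecars is deliberate — desk-scale,
diff-able); no Bayesian or online re-tuning (single-shot tuning mirrors
the offline iterate-and-reprogram workflow); and the patient model's
linearity means phenomena like long-term adaptation or charge-related
side effects are out of scope.
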