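---
title: "Adaptive template-based denoising of HD-MEA recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive template-based denoising of HD-MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-density CMOS microelectrode arrays (HD-MEAs) record extracellular
voltage on thousands of electrodes at once — the default chip model here is
a 64 x 64 grid at 42 um pitch sampled at 14 kHz per electrode. Two kinds of
physiological events are extracted from such recordings: slow local field
potential (LFP) deflections in the ~1–100 Hz band and fast multi-unit
spikes in the ~300–3500 Hz band. Both are routinely contaminated by
structured noise that survives ordinary band-pass filtering because it
lives inside the signal bands: mains pickup, perfusion-driven mechanical
transients, inductive coupling in the chip's readout wiring, spurious
spike-like transients, and failures of the chip's per-electrode
auto-zeroing calibration.

`hdmead` implements an event-level denoising engine for this setting. Its
central idea is that genuine network activity on a dense array has
consistent spatiotemporal statistics — amplitudes, durations, spectral
content, waveform shape, firing rates, burstiness, synchrony across
electrodes — and that a *template* of acceptance intervals derived from the
recording itself separates events that belong to the network from events
that do not. Around that core sit dedicated detectors for the noise
categories that are better caught at the channel or array level than the
single-event level. Crucially, the engine never modifies a single voltage
sample: denoising operates on event labels and channel masks, so everything
outside detected events is left untouched and no signal is ever
"reconstructed".

# Detection

LFP events are detected by hard thresholding of the band-limited signal:
per channel, samples with `|v|` beyond `k` times the channel's noise SD
(default `k = 5`) seed events whose boundaries sit at the threshold
crossings. Events closer than a refractory period (default 100 ms) merge;
durations outside [20 ms, 2 s] are discarded. Both polarities are
detected. Spikes are detected with the precise-timing differential rule:
a spike is declared when the peak-to-peak excursion between a local
minimum and the opposite-sign extremum within one *peak lifetime period*
(default 2 ms) exceeds `k` times the noise SD (default `k = 8`);
detections within 1 ms keep the larger excursion. These defaults are
engineering declarations — exposed in `detection_params()` — not values
inherited from any particular acquisition system.

The per-channel noise SD is the scaled median absolute deviation,
`median(|x - median(x)|)/0.6745`, which estimates the Gaussian background
SD while ignoring the very events being detected; a plain standard
deviation would inflate the threshold on active channels.

## Zero-phase filtering

Event times feed directly into propagation analyses, so filtering must not
shift peaks. The band-pass is therefore applied in the frequency domain
with the *squared* magnitude response of an `order`-4 Butterworth at each
band edge — exactly the magnitude a forward–backward time-domain
Butterworth would have, with identically zero phase. The frequency-domain
route was chosen deliberately: a transfer-function band-pass with a 1 Hz
edge at 14 kHz sampling has poles so close to the unit circle that
`filtfilt` in coefficient form diverges numerically, while the sampled
frequency response is unconditionally stable. The cost is circular
(wrap-around) behaviour at the recording edges, which is immaterial for
recordings that are long relative to the filter's impulse response; the
0.05 s of either end should not be trusted for event timing in very short
recordings.

# The feature template

Six waveform features are computed per event from its snippet: peak-to-peak
amplitude (uV); duration (s, from the detector's threshold crossings);
dominant frequency (periodogram peak, DC excluded); spectral concentration
(fraction of snippet power within +/-1 Hz of the dominant frequency for
LFPs, +/-100 Hz for spikes); shape irregularity; and asymmetry. Shape
irregularity is one minus the fraction of snippet energy captured by its
best-fitting single-lobe Gaussian (fitted by Nelder–Mead over centre and
width, with the amplitude solved analytically as a projection — equivalent
to maximizing the squared cosine between snippet and lobe): smooth
physiological deflections score near 0, jagged broadband artifacts near 1.
Asymmetry is (positive area - negative area)/(total absolute area),
measured about the snippet median so that a DC offset does not move it;
measuring about the mean would force every snippet to zero asymmetry by
construction.

Five activity features are computed per channel: firing rate, burst
frequency (maximal runs of >= 3 events with inter-event gaps <= 100 ms),
synchrony (fraction of the channel's events inside network-event windows —
windows in which at least 5% of electrodes fire within 50 ms for LFPs or
10 ms for spikes), amplitude CV and inter-event-interval CV.

The template stores an acceptance interval per feature: `median +/-
k_mad * MAD` with `k_mad = 3` and the MAD scaled by 1.4826 for Gaussian
consistency (as `stats::mad()` does), so the interval is approximately
+/-3 sigma for well-behaved features. Two robustness guards matter in
practice. First, quantized features (the dominant frequency of fixed-length
spike snippets takes few distinct values) can have MAD exactly zero while
still varying; the interval then falls back to an IQR-based spread before
collapsing to a machine-epsilon pad. Without this guard a knife-edge
interval flags every event whose dominant bin differs from the majority.
Second, `duration` uses the observed min–max range widened by 10% rather
than a MAD interval, since duration distributions are strongly skewed by
the refractory merging.

# Classification and the noise-category flaggers

Two composite rules decide each event:

* **event rule** — at least 2 of the 6 waveform features outside bounds;
* **channel rule** — at least 2 of the 5 activity features outside bounds,
  *or* a metronomic train: ISI CV below 0.2 over at least 10 events. The
  absolute regularity criterion exists because spurious spike trains are
  deliberately built (and observed) to mimic genuine spike waveforms —
  their only reliable signature is non-physiological regularity, and no
  biological multi-unit train approaches an ISI CV of 0.2 (a Poisson train
  has CV 1; even strongly rhythmic units stay well above 0.3).

The violation count (rather than any weighted score) was chosen for
transparency: each decision can be audited feature by feature, and the
`violations` column in the labelled table records it.

Templates are built per modality — pooling LFPs and spikes would put their
wildly different durations and spectra into one interval and blind the
classifier. When a region map is available the engine can be given
per-region templates through `denoise_config(template = list(...))`;
without one, a single template per modality is adapted from the recording.

Four flaggers catch noise that is invisible at the single-event level:

* **line** — a channel whose 49–51 Hz periodogram power exceeds 30% of its
  total 1–100 Hz power is mains-dominated. A white-noise channel
  concentrates only ~2/99 of its band power there, so the margin is wide.
* **mechanical** — the recording is high-passed at 300 Hz (suppressing
  genuine LFP waves, which would otherwise make a large slow wave look
  "simultaneous" across its region), each channel gets a robust amplitude
  threshold, and any 10 ms window in which more than half the array is
  suprathreshold is a transient. Events whose *peak* lies in a flagged
  window are noise; overlap semantics were rejected because a 300 ms
  genuine wave overlapping a 10 ms glitch is not explained by it.
* **inductive** — channels sharing readout wiring (`readout_group`,
  defaulting to the chip column) are correlated in their event-free
  residuals. The residual is taken in the 5–100 Hz sub-band after masking
  a union of all the group's detected event windows (with a margin of
  0.1 s plus half the event duration): large slow deflections leave
  sub-5 Hz baseline-recovery tails far beyond their detected windows, and
  without the sub-band restriction those region-coherent tails dilute the
  coupling correlation. A group of >= 2 channels whose median pairwise
  residual correlation exceeds 0.8 is flagged; singleton groups are
  skipped.
* **calibration** — `|median voltage|` above 100 uV, or more than 5% of
  samples pinned at the channel's extreme values, marks a failed
  auto-zeroing circuit.

When several causes apply to one event the category precedence is
MECHANICAL > LINE > INDUCTIVE > CALIBRATION > SPURIOUS_SPIKE — broad-window
artifacts explain more variance, and the tie-break is deterministic.

Channel-level flags convert *all* events on the affected channels or
windows to noise. This is conservative by design: a mains-saturated
electrode cannot certify any event, including a genuine wave crossing it.

## Idempotence

When the template is adapted from the data, classification is iterated to
a fixed point (at most 5 passes; in practice 2): events flagged as noise
are removed, the template is re-adapted from the remainder, and the loop
stops when nothing changes. The fixed point guarantees that re-applying
`apply_denoising()` to its own cleaned output removes nothing — without
the iteration, the template rebuilt from the cleaned set would differ
slightly from the one that produced it, and borderline events could flip
on re-application.

# The synthetic benchmark

`synth_config()`/`simulate_recording()` generate ground-truth recordings:
Gaussian-windowed negative LFP deflections propagating across rectangular
regions (per-channel onset delay = projected distance / speed), biphasic
spike templates (~1.2 ms, negative-then-positive at a 2:1 lobe ratio) in
Poisson trains with optional 3-spike bursts and ~15% amplitude CV, white
background noise, and the five noise categories with an exact registry of
every contaminated channel/window. All draws derive from one integer seed
via fixed per-stage offsets, so the entire output is a pure function of
the configuration.

The seeded benchmark (`benchmark_config()`) runs at desk scale: a 12 x 12
patch at 42 um pitch, 7.5 kHz sampling, 15 s duration; two regions of
propagating waves (1.5 um/ms, rightward), 34 spiking channels at 3 Hz, and
all five noise kinds on fixed disjoint channel sets. These sizes keep a
full benchmark-plus-baselines run in a few minutes on one CPU while
leaving every mechanism exercised: the propagation front spans ~7 time
bins, each channel sees ~7 LFP events and ~50 spikes, and every flagger
has both positive and negative instances. Full-chip dimensions change
nothing structurally — every algorithm is linear or near-linear per
channel.

What the generator does *not* emulate: biophysical waveform diversity
(only three shape families appear in the clustering fixture), theta/gamma
oscillatory structure, electrode drift, overlapping spikes on one channel,
and spatially graded amplitude decay. Passing the benchmark therefore
demonstrates that the machinery separates the *declared* noise taxonomy
under realistic rates and SNRs, not that the default thresholds transfer
untouched to any particular rig.

## Scoring conventions

Detected events are matched to the registry with semantics mirroring the
engine's: sustained contamination (line, inductive, calibration) claims
every event overlapping its window on its channel; transients (mechanical,
spurious) claim events peaking inside them. Detector false alarms that
match neither registry are excluded from the confusion counts and reported
separately.

For the method comparison against the classical baselines (causal FIR,
Savitzky–Golay, db4 wavelet with soft universal threshold, Fourier notch),
each per-channel event stream is scored against the *recoverable* truth —
injected events not swallowed by sustained contamination, since no
event-labelling method can certify an event on a mains-saturated
electrode. The per-channel SNR is (RMS of recoverable-truth rate + c) /
(RMS of residual rate + c), where c is the one-event quantization floor of
the binned series; the floor keeps perfectly recovered channels finite and
is identical across methods. The paper-style mean/std rate SNR
(`snr_distribution()`) is also computed and reported; on sparse desk-scale
count series it mostly measures bin occupancy, which is why the
truth-referenced ratio drives the baseline comparison.

Center-of-activity trajectories (CATs) are activity-weighted centroids of
electrode positions per time bin. The benchmark reports the least-squares
propagation direction error against the injected direction, and the mean
CAT distance from the clean-data trajectory before and after denoising,
per modality and overall. The LFP-side deviation carries a small
*footprint cost* — removing a contaminated electrode wholesale shifts
centroids slightly — while the spike side gains strongly from removing
dense spurious trains; the recording-level (mean over modalities)
comparison is the meaningful directional claim.

# Waveform clustering

Snippets are aligned at their largest-magnitude extremum, padded or
truncated to a fixed window (1 s LFP / 4 ms spikes) and scaled to unit
peak — shape clustering must be amplitude-invariant because amplitude is
already a template feature. PCA retains >= 90% variance (capped at 10
components); clustering is flat-kernel mean-shift with the bandwidth
defaulting to the 0.3 quantile of pairwise distances of a deterministic
25% subsample (every 4th point). Mean-shift infers the cluster count from
density; modes closer than half a bandwidth merge, labels are ordered by
decreasing cluster size, and the whole pipeline is deterministic given its
inputs. Cluster quality is the mean silhouette `(b - a)/max(a, b)`;
singleton clusters score 0, and a single-cluster partition is an error
rather than a silhouette of convenience.

# Numerical and interface conventions

* Channels are 0-based and row-major (`channel = row * n_cols + col`),
  matching the on-disk layout; voltages are quantized to float32 on
  construction so in-memory values equal stored values and file
  round-trips are bit-exact.
* Times are double seconds with half-open event windows `[t_on, t_off)`.
* Event tables are CSV with a long-format CSV sidecar for waveform
  snippets; numeric fields print with 17 significant digits so doubles
  round-trip exactly. Templates serialize to JSON at full precision, so a
  reloaded template makes bit-identical decisions.
* All randomness lives in the generator; detection, the engine, the
  baselines and the clustering are deterministic.

# Limitations

The engine is batch, not streaming: the template adapts per recording, not
per waveform in real time. Template statistics need tens of events per
modality to be meaningful — on very short recordings (a few seconds, a
handful of LFP events per channel) the robust intervals become erratic and
the event rule over-rejects; channel-level features are guarded by a
minimum event count, but the event-level intervals are not, so recordings
should be long enough for >= 100 events per modality (the engine refuses
to adapt a template below 10). Thresholds are declared defaults, not values
fitted to any instrument. The violation-count rule treats features as
exchangeable evidence; a weighted or learned combination could be sharper
but would lose auditability. Inductive detection assumes the readout
grouping is known (or that the column default applies); a wrong grouping
degrades it to a no-op rather than producing false flags, since unrelated
channels decorrelate. Finally, channel-level removal is deliberately
all-or-nothing per category — partial trust in a contaminated electrode is
out of scope.
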