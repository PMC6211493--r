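---
title: "Online ERD estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online ERD estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdlia)
```

## The problem

During kinesthetic motor imagery, the alpha-band (8–13 Hz) rhythm over
the contralateral sensorimotor cortex loses power relative to rest —
event-related desynchronization (ERD). ERD magnitude indexes
corticospinal excitability, which makes it an attractive trigger signal
for brain-state-dependent stimulation: deliver a TMS pulse the moment
the instantaneous ERD crosses a target magnitude. The catch is latency.
Any causal power estimator trades smoothing against delay, and a trigger
fed by a slow estimator fires on a brain state that has already passed.

`erdlia` implements and compares two causal estimators of alpha power at
a participant-specific frequency of interest (FOI):

* **Sliding-FFT PSD** (`erd_fft_trace()`), the conventional pipeline:
  1-s windows with 99% overlap, one Hanning-tapered periodogram per
  window, power read at the FOI bin.
* **Lock-in amplifier (LIA)** (`erd_lia_trace()`): a causal
  second-order Butterworth band-pass at FOI ± 1 Hz, then point-by-point
  multiplication with quadrature reference sinusoids at the FOI and
  integration over 1/FOI-s windows with 99% overlap — the lock-in
  amplifier scheme, recovering the instantaneous narrowband amplitude
  from windows one carrier period long instead of a full second.

Both feed the same transform against a rest baseline `R` at the FOI:

$$\mathrm{ERD}(f,t) = \frac{A(f,t) - R(f)}{R(f)} \times 100,$$

negative during suppression, with floor −100. Throughout the package a
"threshold of 35%" means the signed condition `erd <= -35`.

## Conventions that matter

**Causality and trailing-edge stamps.** Every estimate is stamped at
the time its last input sample was acquired. The FFT estimator's 1-s
window therefore *shows* its intrinsic delay in the trace, which is the
entire point of the comparison. Zero-phase (forward–backward) filtering
is deliberately absent from the online path.

**Amplitude versus power.** The lock-in output
`2 * sqrt(I^2 + Q^2)` is the peak amplitude of a sinusoid (the factor 2
undoes the 1/2 mean of sin²); it is squared before the ERD transform so
both pipelines live on one power scale and their noiseless steady
states agree analytically. The quadrature (sin + cos) pair makes the
magnitude independent of the unknowable EEG phase; a single-reference
lock-in would not be usable here.

**PSD normalization.** Periodogram bins are scaled by the taper's
coherent gain (`2 |X_k|^2 / (\sum w)^2`), so a bin-centred sinusoid
reads its mean-square power under any taper; with the rectangular taper
this coincides with the Parseval normalization. The convention cancels
in the ERD ratio but keeps absolute powers interpretable against the
generator's ground truth. The taper is the periodic Hann window.

**Baseline.** `compute_baseline()` pools mean power over the 3–5 s
sub-window of every rest phase, computed by the *same* pipeline that
produces the instantaneous power — baselines are not interchangeable
between estimators because their absolute scales differ. Pooling across
all rest phases of a session (rather than per trial) is the default.
`run_session()` prepends one fixed 8-s calibration rest for this
purpose, because the protocol's randomized 4–6 s rests are shorter than
the 5 s the 3–5 s window needs.

**FOI selection.** `select_foi()` replaces visual inspection with a
deterministic rule: the frequency in 8–13 Hz whose trial-averaged
task-phase ERD is most negative, ties broken toward the lower
frequency. `screening_spectra()` produces its input from a screening
recording.

**FOI bin mapping.** The FFT pipeline maps the FOI to the nearest bin
and raises a configuration error if the FOI falls between bins (more
than a quarter of the bin spacing away); with the default 1-s window,
integer FOIs are exact.

**Overlap settings.** The protocol descriptions this emulates disagree
internally about the FFT overlap (99% in the algorithm description, 90%
in the session description). The default is 99%; `fft_overlap` is an
explicit `estimator_config()` field so either can be run, and the
conflict is not silently resolved.

## The synthetic generator

`synth_eeg()` is first-class, tested code: an alpha carrier
`a(t) sin(2π f t + φ)` whose envelope drops from the rest amplitude to
`sqrt(1 - depth/100)` of it during task phases (instantaneous by
default, or a linear ramp), plus seeded white or 1/f-amplitude pink
background noise. Depth is defined on *power*, so "depth 70" means a
perfect estimator reads −70%. The exact envelope — and hence the true
ERD at every sample — is returned with the recording.

SNR is specified as rest-phase carrier power divided by the realized
noise power in the 8–13 Hz alpha band, with the noise scaled per
realization from its own periodogram, so the requested SNR is exact for
every seed. The headline benchmark conditions are pink noise at
alpha-band SNR 10, FOI 10 Hz, depth 70%, 50 seeds.

What the generator does *not* emulate: non-sinusoidal and non-stationary
rhythms, mu/beta harmonics, eye and muscle artifacts, electrode drift,
volume-conducted interference, or amplifier characteristics. Passing
tests therefore demonstrate the estimators' signal-processing
properties under controlled conditions, not clinical performance on
real EEG.

`synth_emg_mep()` emulates the excitability side: each simulated pulse
evokes one damped-sine MEP whose peak-to-peak amplitude is
`baseline * (1 + gain * |ERD|)` times a log-normal trial factor, on top
of Gaussian EMG noise, with an optional fraction of epochs given
pre-stimulus activity above the ±20 µV rejection limit. The waveform is
a single 150 Hz cycle — clear of the 50 Hz notch and inside the EMG
passband; its shape is irrelevant to peak-to-peak metrics.

## Trigger simulation

`run_trial()` fires at the *first* stamped sample inside the task phase
with `erd <= -threshold` — no debouncing or hold time, at most one
stimulus per trial, unsuccessful trials are counted but never
stimulated. `run_session()` alternates seeded uniform 4–6 s rests with
5-s task phases, runs the condition's estimator causally over the
generated recording, and stops at 25 successful trials (or at a
configurable 100-trial cap, flagging the result incomplete — the cap is
a simulation necessity, not part of the emulated protocol). The
`RELAXED` control draws one stimulus time uniformly in each task phase.

## MEP analysis

EMG epochs span −50 to +150 ms around the stimulus at 2 kHz. The
preprocessing is a causal second-order Butterworth band-pass with a
50 Hz band-stop notch. The nominal acquisition band reaches 1000 Hz —
exactly Nyquist at the 2 kHz trial rate — so the digital default caps
the upper edge at 990 Hz; requesting an edge at or above Nyquist is an
error. Rejection is strict: a trial is discarded if any pre-stimulus
sample exceeds 20 µV in absolute value (exactly 20 µV is kept); the
rule reads only pre-stimulus samples, so it commutes with measurement.
Peak-to-peak is max − min in a 10–150 ms post-stimulus search window:
the epochs themselves start at −50 ms, and the 10 ms guard excludes the
stimulus artifact; both bounds are arguments. Accepted amplitudes are
normalized by the mean accepted amplitude of the rest condition, and
per-condition means and sample SDs are reported.
`stimulus_intensity()` computes the 120%-of-rMT pulse intensity,
rounded half away from zero to integer %MSO, which reproduces all 17
rows of the shipped screening table (`participant_table()`).

## The benchmark and its delay criterion

How fast an estimator "detects" a step has no canonical definition, and
the printed delay figures this package is compared against come from a
criterion that is not public. The package's declared operationalization:
per seed, delay is the time from the true envelope step to the first
trace sample reaching 50% of the trace's *own* steady-state change
(criterion configurable among 25/50/90%). The pre-step reference is the
mean over the settled 2 s before the step — excluding the band-pass
start-up transient, which would otherwise bias the criterion level —
and the steady state is measured from two analysis windows after the
step to the task end.

Under this criterion the noiseless delays are ~469 ms for the FFT
(crossing the Hanning-weighted half-window) and ~251 ms for the LIA
(~202 ms for the band-pass envelope to cross the 50%-power point plus
~50 ms from the trailing-edge integration window). With the headline
noise conditions the 50-seed means land near 460–500 ms and
200–300 ms: the ordering is stable (the LIA is faster in essentially
every comparison), while the LIA point value sits above the 200 ms a
steeper criterion would produce — an honest consequence of the declared
50% rule rather than a parameter to adjust.

Accuracy is the RMS error between estimated and true ERD over the
steady segment pooled over seeds; stability is the within-segment SD
averaged over seeds. One finding deserves emphasis: at equal
stationary-noise SNR with these default configurations, the FFT trace
is slightly *more* stable than the LIA trace. The equivalent noise
bandwidth of the second-order Butterworth FOI ± 1 Hz band-pass is about
2.2 Hz versus about 1.5 Hz for a 1-s Hanning periodogram bin, and the
1/FOI integration window is far too short to average narrowband noise
whose correlation time is ~0.5 s. Any filter with a ±1 Hz passband has
ENBW above 1.5 Hz, so under stationary Gaussian noise the claimed
stability advantage of the lock-in estimator is not reachable with
these parameters; its genuine advantage in this model is latency. The
corresponding acceptance check asserts the literature's direction and
is allowed to fail, documenting the discrepancy rather than hiding it.

## Numerical choices and degenerate inputs

* Hops are `max(1, round(n (1 - overlap)))` samples; 99% overlap gives
  10 ms hops for the FFT and 1 ms for the LIA at 1 kHz.
* The LIA integration window is `round(rate/FOI)` samples; at FOIs that
  do not divide the rate the window is one sample off a carrier period,
  producing sub-0.1% ripple that the baseline (same pipeline) cancels.
* Signals shorter than one analysis window raise insufficient-data
  errors; `R <= 0` baselines, out-of-band filter edges and empty search
  windows are configuration errors, not silent NaNs.
* EDF I/O quantizes to 16 bits over each channel's physical range;
  round-trips are exact for CSV and within one quantization step for
  EDF. Constant channels get an artificially widened range to keep the
  scale factor finite.
* `run_trial()` tolerates one output hop of slack at the trailing edge
  of a task phase, since trailing-edge stamps are discrete.
* Problem sizes used by the shipped tests and the acceptance script
  (12–16 s fixtures, 10–50 seeds, 25-trial sessions) were chosen as the
  smallest sizes at which the stochastic checks are reproducible.

## Known limitations

* The stability comparison above: the lock-in pipeline's advantage is
  delay, not variance, under stationary noise.
* Delay estimates from single noisy traces are heavy-tailed; seed-set
  means move by ±30 ms. The benchmark reports per-seed values so users
  can inspect the distribution.
* The 10-20 montage ships only schematic coordinates and the C3/C4/Cz
  large-Laplacian rings; dense-array layouts must be supplied as JSON.
* The EDF subset covers continuous recordings with one common sampling
  rate; annotations and discontinuous files are out of scope.
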