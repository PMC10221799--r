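---
title: "Methods: modelling a wrist-worn sEMG acquisition system at the desk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a wrist-worn sEMG acquisition system at the desk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgtwin)
```

## What the package models

`emgtwin` is a desk-scale digital twin of a four-channel wrist-worn surface
electromyography (sEMG) acquisition system: synthetic electrode-level sEMG,
the three-stage analog conditioning chain, a 16-bit bipolar ADC with a framed
binary link protocol, and the two analyses such a device exists for —
muscle-fatigue trend detection and four-class gesture recognition.  Every
stage is testable without any recorded human data because the generator
produces signals with the statistical features the analyses rely on.

## The synthetic sEMG generator

Surface EMG is well approximated, for amplitude- and spectrum-level
analyses, by band-limited Gaussian noise under a slowly varying contraction
envelope.  Physiological references put the electrode-level peak-to-peak
amplitude at 0–6 mV and the bulk of the spectral energy between 30 and
300 Hz, which are the generator's defaults (`base_amplitude = 2 mV`,
`band_low = 30`, `band_high = 300`).

Per channel the carrier is white Gaussian noise shaped by two cascaded
two-corner Butterworth band-pass sections (eighth order in total).  A single
four-pole two-corner section was considered first, but its skirts leave only
about 78% of the carrier power inside the nominal band; the cascaded pair
reaches about 93%, which is what "energy mainly in 30–300 Hz" should mean
for a generator whose consumers integrate band power.  The carrier is
normalised to unit RMS block-wise and scaled so that its 99.9% Gaussian
excursion equals the burst envelope

\[ e(t) = \tfrac{A}{2}\,(1 + \alpha t)\,\mathrm{burst}(t), \]

with `A = base_amplitude`, amplitude growth rate `alpha = fatigue_amp_rate`
(fraction/s), and a rectangular burst gate with 10 ms raised-cosine ramps
(the ramps avoid spectral splatter from hard edges; the gate shape itself is
not specified by the hardware's experiments).  Because extremes of a
Gaussian process grow with observation length, the realised peak-to-peak of
a multi-second burst sits slightly above `A` (≈ 2.3 mV for a 2 mV setting);
tests assert the containment band, not an exact extreme.

Fatigue compresses both band corners by \(c(t) = 1 - \gamma t\)
(`gamma = fatigue_compress_rate`), applied piecewise over 0.5 s blocks with
0.2 s of filter pre-roll so block boundaries carry no start-up transients.
Scaling both corners scales the whole carrier spectrum, so the median
frequency falls proportionally to \(c(t)\) — the canonical spectral
signature of fatigue — while \(1+\alpha t\) raises the RMS.  The default
fatigue session (`fatigue_session_config()`) uses the intermittent-force
protocol of the validation experiments: 2 s force cycles with 1 s of force,
60 s long, `alpha = 0.02`/s and `gamma = 0.005`/s, values chosen so that a
one-minute session shows an unmistakable but physiologically modest trend
(amplitude up ×2.2, median frequency down 30%).

Interference terms are added last: a 50 Hz power-line sinusoid with a common
random phase across channels (0.1 mV default), low-pass-filtered noise below
1 Hz as baseline drift / motion artifact (0.2 mV RMS), and a white sensor
noise floor (10 µV RMS).  All randomness flows from one seed through
independent substreams per channel and per interference source, so a
configuration reproduces bit-identically and channels are independent.

What the generator does *not* emulate: motor-unit action potentials and
their firing statistics, electrode–skin impedance, inter-muscle crosstalk,
or amplitude distributions heavier-tailed than Gaussian.  Tests passing on
this generator therefore validate the *pipeline* — filters, codec,
estimators, classifier plumbing — not claims about real muscles.

## The analog conditioning chain

The three stages are modelled as continuous-domain rational transfer
functions:

* **Stage 1** — instrumentation amplifier, flat differential gain
  `g1 = 100` V/V, followed by a passive first-order high-pass at 15 Hz:
  \(H_1(s) = g_1 s / (s + \omega_{hp})\).  The amplifier chip's bandwidth is
  far above the signal band, so it is treated as ideal; common-mode paths
  are not modelled.  First order is assumed for the passive high-pass (a
  single RC section is the natural reading of "passive high-pass filter").
* **Stage 2** — fourth-order Butterworth low-pass, −3 dB at 500 Hz, passband
  gain `g2 = 17.8` V/V.  The hardware realises it as two cascaded
  second-order sections; the ideal fourth-order prototype is modelled, which
  reproduces the designed −40 dB point at 1.6 kHz
  (\(-10\log_{10}(1+(1600/500)^8) = -40.4\) dB).
* **Stage 3** — active twin-T notch at 50 Hz,
  \(H_3(s) = G (s^2+\omega_0^2)/(s^2 + (\omega_0/Q) s + \omega_0^2)\) with
  \(Q = 1/(2(2-G))\).  The design gain is `g3 = 1.4` V/V (so `Q = 0.833`).
  The feedback resistor pair stored in the configuration (`ra = 400`,
  `rb = 1000` ohms) is informational: inserting it into `G = 1 + rb/ra`
  gives 3.5, which contradicts both the stated 1.4 V/V and the requirement
  `G < 2` for a positive Q, so the resistors are taken as swapped in the
  design description and `g3` is authoritative.

The nominal passband gain of the cascade is `g1·g2·g3 = 2492` V/V.  Note the
measured mid-band gain of a real cascade sits slightly lower (the notch's
shoulders reach into the passband: at 150 Hz the model gives ≈ 2261 V/V),
which is why acceptance checks compare the *nominal product* read off the
stage transfer functions, and quote 50 Hz rejection relative to the 150 Hz
mid-passband gain.  Attenuation *at* 50 Hz is exactly zero transmission by
construction; the finite number quoted for power-line rejection is the worse
of the 49.5/50.5 Hz band edges (≈ −35 dB, comfortably below the −30 dB
design line).

Time-domain filtering (`apply_frontend()`) discretizes each stage by the
bilinear transform with stage-specific prewarping (high-pass corner,
low-pass corner, notch centre) and requires the input rate to be at least
`10 × f_lp`; the generator's 20 kHz default leaves the 0–1.6 kHz region of
interest faithful.  Steady-state sinusoid gains match the continuous
response within 1% after a `5/f_hp` start-up transient, and all acceptance
checks evaluate the continuous response, so the discretization choice never
touches them.

## ADC and frame codec

The converter model is a mid-tread two's-complement quantizer,
`code = clamp(round(v/LSB))` with `LSB = 2·v_range/2^bits`, defaults 16 bits
over ±5 V at 2 kHz — the ±5 V span chosen so a 2 mV peak-to-peak electrode
signal times the 2492 V/V cascade spans the range.  Decimation from the
synthesis rate uses an eighth-order Butterworth anti-alias low-pass at
`0.45 · fs_adc` before keeping every k-th sample (an idealisation of the
converter's internal anti-aliasing).

Each acquisition frame is 112 bits: a 16-bit sync word (`0xAA55`), four
16-bit big-endian two's-complement samples, and a 32-bit trailer made of a
24-bit rolling counter and an 8-bit parity byte (XOR of all payload and
counter bytes, i.e. even parity per bit lane).  The 16/64/32 split is fixed
by the published link arithmetic — 2000 Hz × 112 bit = 224,000 bit/s, inside
the configured 230,400 bit/s link — while the sync word and trailer layout
are this implementation's protocol dialect (the hardware documents parity
checking but not its placement).  The decoder scans for sync, validates
parity, and resumes byte-by-byte after corruption, so it is
self-synchronizing; losses are counted from counter-continuity gaps plus
unparseable leading/trailing regions at one frame per 14 bytes rounded up,
which makes a truncated final frame corrupt rather than fatal.

## Fatigue analysis

`fatigue_report()` composes four estimators, mirroring the device's
validation experiments:

* **Windowed RMS** over non-overlapping 2000-sample windows (1 s at 2 kHz),
  normalised per channel.  Normalisation is by the channel maximum by
  default (series in [0, 1]; a sum option exists) — the method of
  normalisation is a documented choice, as only "with normalization" is
  specified by the experiments being emulated.
* **Upper-boundary extraction**: during intermittent force the window RMS
  values are bimodal (force vs rest).  A one-dimensional two-means
  iteration, initialised at the series minimum and maximum, returns the
  upper cluster; initialisation at the extremes makes it deterministic.  A
  pre-check compares the largest gap between sorted values against the
  uniform spacing (ratio ≥ 3 declares bimodality); without bimodal structure
  the method warns and falls back to a midpoint threshold, which is also the
  path a sustained-effort session takes.
* **Trend fits**: ordinary least squares of normalised RMS against window
  index over the active windows, per channel.  Window index (not sample
  index) is the abscissa; the sign of the slope — the quantity of interest —
  is unaffected by that choice.
* **Median frequency** from a Hann-windowed STFT (2000-sample windows, 50%
  overlap): per frame, the smallest frequency where cumulative power within
  15–500 Hz reaches half the band total, linearly interpolated between bins.
  Zero-power frames yield `NA` and are excluded from fits.  For an
  intermittent protocol the MF trend is fitted over active frames only
  (selected by the same two-means rule applied to frame power); a sustained
  session uses all frames.

The expected behaviour under the generator: RMS slope positive on all
channels and MF slope negative for any session with `alpha, gamma > 0`, and
both statistically indistinguishable from zero for null sessions.  The null
noise floor was quantified over 20 independent null sessions (60 s,
defaults): |mean RMS slope| stays below 5·10⁻⁴ per window and |MF slope|
below 0.11 Hz/frame; unit tests assert five times those spreads.

## Gesture recognition

The recognition pipeline is: epoching (250 ms, 50% overlap — the epoching of
the original experiments is unstated, so the field's conventional values are
used) → five time-domain features per channel (MAV, RMS, zero crossings,
slope-sign changes, waveform length; ZC and SSC use a dead band of 3× a
robust per-epoch noise-σ estimate from the median absolute second
difference) → standardised PCA retaining 95% of variance with a
deterministic sign convention → a distance-ordered binary tree of three
soft-margin binary SVMs (linear kernel, C = 1; RBF available).

Feeding raw 2 kHz samples to PCA was considered and rejected: at that rate
raw-sample principal components are noise-dominated, and the time-domain
feature set is the standard front end for myoelectric SVM classification.
The tree is built exactly as the device's classifier: the two closest
classes (Euclidean centroid distance in PCA space) train the deepest
separator and merge; the merged super-class trains the next separator
against its nearest remaining class and merges again; the root separates the
final two super-classes.  Distance ties break toward the smallest class
label.  Prediction walks from the root, emitting a leaf as soon as a node
assigns its non-merged side.  Inter-class distance is centroid-based (a
medoid variant would also be defensible; centroids keep merged-class
distances exact and cheap).

The synthetic gesture dataset gives each of the four gestures a distinct
channel-activation pattern (the fist/open rows are deliberately the closest
pair, so the default tree reproduces the A-B-first merge order of the
device's classifier), a per-trial lognormal effort jitter (sdlog 0.15,
shared across channels — trial-to-trial effort variability that preserves
the activation *pattern*), and a 0.2 mV RMS additive noise floor against
which the `separability` parameter scales the contrast.  Trials are 1 s at
2 kHz with power line and drift off, emulating conditioned signals referred
back to electrode scale — the notch and high-pass remove those terms before
any classifier sees real data.  Evaluation uses stratified 70/30 trial
splits; the headline figure is the mean held-out accuracy over ten seeds,
which on the default dataset (separability 3, 40 trials per class) sits at
the high end of what the physical system reports on human subjects.  That
is a property of the synthetic construction, not a claim about subjects:
the dataset is built to be separable at that setting.

## Numerical choices and degenerate inputs

* Transfer functions are stored as real polynomial coefficient vectors;
  construction rejects improper or unstable functions (poles must sit
  strictly in the left half-plane).  Cascade magnitudes equal the product of
  stage magnitudes to 10⁻⁹ over 1 Hz–5 kHz.
* The quantizer clamps out-of-range inputs and reports a saturation count
  rather than erroring; `round` half-to-even ties are inherited from base R
  and sit on a measure-zero set of inputs.
* Zero-duration configurations produce empty traces; all-zero channels
  produce zero normalized RMS with a warning instead of dividing by zero;
  degenerate (all-equal) boundary inputs return all indices with a warning.
* Problem sizes in the test suite are chosen to keep a laptop-scale run:
  20 fatigue sessions of 60 s and 10 gesture seeds of 160 one-second trials
  for the end-to-end checks, shorter traces for unit-level contracts.

## Known limitations

The twin reproduces design values, not hardware non-idealities: measured
gains of the physical channel (e.g. its steeper-than-ideal roll-off above
700 Hz), equivalent input noise, latency, radio range and power figures are
outside the model.  The BLE radio itself is out of scope — the codec models
framing, parity and loss accounting, not timing.  Fatigue metrics are
trend detectors, not physiological fatigue indices; no endurance-time or
threshold interpretation is offered.  Cross-subject generalisation of the
gesture classifier cannot be studied on this generator, which has no notion
of a subject beyond the seed.
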