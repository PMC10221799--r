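# emgtwin

A desk-scale digital twin of a wrist-worn, four-channel surface
electromyography (sEMG) acquisition system, written for signal-processing
and wearable-electrophysiology work where the real hardware (or recorded
data) is not at hand but the full acquisition-and-analysis chain must be
exercised, tested and characterized.

The package models the whole chain as composable pieces:

* **Synthesis** — band-limited Gaussian sEMG (0–6 mV peak-to-peak, energy
  mainly in 30–300 Hz) with burst envelopes, fatigue progression
  (amplitude growth `1 + αt`, spectral compression `1 − γt`), 50 Hz
  power-line pickup, baseline drift and sensor noise; plus labelled
  four-gesture datasets.
* **Analog front end** — the three conditioning stages as continuous
  transfer functions: instrumentation amplifier (gain 100 V/V) with a 15 Hz
  passive high-pass, a fourth-order Butterworth low-pass (−3 dB at 500 Hz,
  gain 17.8 V/V), and an active twin-T 50 Hz notch with
  `Q = 1/(2(2 − G))`, `G = 1.4` — a nominal passband product of
  `100 × 17.8 × 1.4 = 2492` V/V.
* **ADC + codec** — 16-bit bipolar two's-complement quantization at 2 kHz
  and a 112-bit acquisition frame (sync word, 4 × 16-bit samples, 24-bit
  counter, parity byte): 2000 Hz × 112 bit = 224,000 bit/s, with a
  self-synchronizing decoder and packet-loss accounting.
* **Fatigue analysis** — normalized 2000-sample windowed RMS,
  two-means extraction of the active (force) windows, least-squares trend
  fits, and an STFT median-frequency track: rising RMS with falling MF is
  the fatigue signature.
* **Gesture recognition** — time-domain features (MAV, RMS, ZC, SSC, WL),
  PCA to 95% variance, and a distance-ordered binary tree of three binary
  SVMs: the closest class pair trains the deepest separator and is merged,
  recursively, exactly as the wearable's four-gesture classifier.

Everything is a tibble in, tibble out where data is tabular; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

## A worked example

Run one fatiguing-contraction session through the entire twin — generation,
analog conditioning, ADC framing, decoding, analysis:

```r
library(emgtwin)

cfg <- pipeline_config(synth = fatigue_session_config(seed = 2))
res <- run_fatigue_pipeline(cfg)

res$decode
#> # decode_report: 120000 ok, 0 corrupt (loss 0%), 0 bytes skipped

res$report
#> # fatigue_report
#>   RMS slope per channel: 0.00829, 0.00835, 0.00824, 0.00839
#>   MF slope (channel mean): -0.344 Hz per frame

glance(res$report)
#> # A tibble: 1 × 5
#>   n_windows mean_rms_slope all_rms_slopes_positive mf_slope fatigue_signature
#>       <int>          <dbl> <lgl>                      <dbl> <lgl>
#> 1        60        0.00832 TRUE                      -0.344 TRUE
```

All four channels show a positive normalized-RMS trend (~0.008 per 1 s
window: amplitude grows as the simulated muscle tires) and the median
frequency falls (~0.34 Hz per STFT frame: the spectrum compresses toward
low frequencies) — the two canonical markers of muscle fatigue, recovered
through the full acquisition model with zero frame loss.

The gesture side in one call:

```r
run_gesture_pipeline(seed = 1)$accuracy
#> [1] 1
```

and the analog chain's frequency response:

```r
tbl <- bode_table(frontend_config())
dplyr::filter(tbl, stage == "cascade", abs(freq - 50) < 1)[, 1:4]
# the 50 Hz notch: > 30 dB below the mid-passband gain
```

A thin command-line wrapper over these functions ships in
`inst/cli/emgtwin.R` (`simulate`, `bode`, `encode`, `decode`, `fatigue`,
`gesture`, `pipeline`).

## Documentation

The methods vignette (`vignettes/emgtwin-methods.Rmd`) documents the
generator's model and its deliberate simplifications, the transfer-function
derivations, the frame-protocol dialect, the estimator definitions, and the
package's numerical and design choices.
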