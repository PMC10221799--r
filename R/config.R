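#' Synthetic sEMG generator configuration
#'
#' Bundles every knob of the synthetic surface-EMG generator.  The defaults
#' describe a four-channel wrist recording: electrode-level peak-to-peak
#' amplitude inside the physiological 0--6 mV range, spectral energy
#' concentrated in 30--300 Hz, an intermittent-force burst pattern with a 2 s
#' cycle and 1 s of force, 50 Hz power-line pickup, slow baseline drift and a
#' white sensor-noise floor.  Fatigue is modelled by a linear amplitude growth
#' `(1 + fatigue_amp_rate * t)` of the burst envelope together with a linear
#' compression `c(t) = 1 - fatigue_compress_rate * t` of both band corners,
#' which drags the median frequency down proportionally.
#'
#' @param n_channels Number of electrode channels.
#' @param fs_synth Internal generation rate in Hz.  Kept well above the 2 kHz
#'   acquisition rate so the analog conditioning chain can be emulated before
#'   ADC decimation.
#' @param duration Trace length in seconds.
#' @param base_amplitude Electrode-level peak-to-peak amplitude in volts of a
#'   full-effort burst at `t = 0` (physiological range 0--6 mV).
#' @param band_low,band_high Corner frequencies in Hz of the band-pass shaping
#'   applied to the Gaussian carrier.
#' @param burst_period,burst_duration Force cycle and force duration in
#'   seconds.  `burst_duration == burst_period` means continuous effort.
#' @param fatigue_amp_rate Fractional amplitude growth per second (0 = none).
#' @param fatigue_compress_rate Fractional band-corner compression per second
#'   (0 = none); `fatigue_compress_rate * duration` must stay below 1.
#' @param powerline_amp Amplitude in volts of the power-line sinusoid.
#' @param powerline_freq Power-line frequency in Hz.
#' @param drift_amp RMS amplitude in volts of the low-frequency baseline
#'   drift (motion artifact).
#' @param drift_corner Low-pass corner in Hz of the drift process.
#' @param noise_amp RMS amplitude in volts of the white measurement noise.
#' @param seed Integer seed; every random stream in the generator derives
#'   from it, so identical configurations give bit-identical traces.
#' @return An object of class `synth_config`.
#' @seealso [generate_semg()], [generate_fatigue_session()],
#'   [generate_gesture_dataset()]
#' @export
synth_config <- function(n_channels = 4,
                         fs_synth = 20000,
                         duration = 10,
                         base_amplitude = 2e-3,
                         band_low = 30,
                         band_high = 300,
                         burst_period = 2,
                         burst_duration = 1,
                         fatigue_amp_rate = 0,
                         fatigue_compress_rate = 0,
                         powerline_amp = 1e-4,
                         powerline_freq = 50,
                         drift_amp = 2e-4,
                         drift_corner = 1,
                         noise_amp = 1e-5,
                         seed = 1L) {
  check_number(n_channels, "n_channels", lower = 1)
  check_number(fs_synth, "fs_synth", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0)
  check_number(base_amplitude, "base_amplitude", lower = 0)
  check_number(band_low, "band_low", lower = 0, strict_lower = TRUE)
  check_number(band_high, "band_high", lower = 0, strict_lower = TRUE)
  if (!(band_low < band_high && band_high < fs_synth / 2)) {
    abort_config("need band_low < band_high < fs_synth / 2")
  }
  check_number(burst_period, "burst_period", lower = 0, strict_lower = TRUE)
  check_number(burst_duration, "burst_duration", lower = 0)
  if (burst_duration > burst_period) {
    abort_config("burst_duration must not exceed burst_period")
  }
  check_number(fatigue_amp_rate, "fatigue_amp_rate", lower = 0)
  check_number(fatigue_compress_rate, "fatigue_compress_rate", lower = 0)
  if (fatigue_compress_rate * duration >= 1) {
    abort_config(
      "fatigue_compress_rate * duration must stay below 1 (band collapses)")
  }
  for (nm in c("powerline_amp", "drift_amp", "noise_amp")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(powerline_freq, "powerline_freq", lower = 0,
               strict_lower = TRUE)
  check_number(drift_corner, "drift_corner", lower = 0, strict_lower = TRUE)
  structure(
    list(n_channels = as.integer(n_channels), fs_synth = fs_synth,
         duration = duration, base_amplitude = base_amplitude,
         band_low = band_low, band_high = band_high,
         burst_period = burst_period, burst_duration = burst_duration,
         fatigue_amp_rate = fatigue_amp_rate,
         fatigue_compress_rate = fatigue_compress_rate,
         powerline_amp = powerline_amp, powerline_freq = powerline_freq,
         drift_amp = drift_amp, drift_corner = drift_corner,
         noise_amp = noise_amp, seed = as.integer(seed)),
    class = "synth_config")
}

#' Analog front-end configuration
#'
#' Design values of the three-stage conditioning chain: an instrumentation
#' amplifier (gain `g1`, set in hardware by a 499 ohm gain resistor) followed
#' by a passive first-order high-pass at `f_hp`; a fourth-order Butterworth
#' low-pass at `f_lp` with in-band gain `g2`; and an active twin-T notch at
#' `f_notch` with positive-feedback gain `g3`.  The notch quality factor
#' follows Q = 1 / (2 (2 - G)) with G = `g3`, so `g3` must stay below 2.
#' The nominal passband gain of the cascade is `g1 * g2 * g3` = 2492 V/V with
#' the defaults.  `ra`/`rb` are the feedback divider resistors of the notch
#' stage and are informational: `g3` is authoritative for the gain.
#'
#' @param g1 First-stage differential gain (V/V).
#' @param r_gain Instrumentation-amplifier gain resistor in ohms
#'   (informational).
#' @param f_hp High-pass corner in Hz (first order, passive).
#' @param lp_order Butterworth low-pass order (even).
#' @param f_lp Low-pass -3 dB corner in Hz.
#' @param g2 Second-stage passband gain (V/V).
#' @param f_notch Notch center frequency in Hz.
#' @param g3 Notch-stage positive feedback gain G (V/V), must be `< 2`.
#' @param ra,rb Notch feedback resistors in ohms (informational).
#' @return An object of class `frontend_config`.
#' @seealso [tf_stage1()], [tf_stage2()], [tf_stage3()], [apply_frontend()]
#' @export
frontend_config <- function(g1 = 100, r_gain = 499, f_hp = 15,
                            lp_order = 4, f_lp = 500, g2 = 17.8,
                            f_notch = 50, g3 = 1.4,
                            ra = 400, rb = 1000) {
  check_number(g1, "g1", lower = 0, strict_lower = TRUE)
  check_number(f_hp, "f_hp", lower = 0, strict_lower = TRUE)
  check_number(f_lp, "f_lp", lower = 0, strict_lower = TRUE)
  check_number(g2, "g2", lower = 0, strict_lower = TRUE)
  check_number(f_notch, "f_notch", lower = 0, strict_lower = TRUE)
  check_number(lp_order, "lp_order", lower = 2)
  if (lp_order %% 2 != 0) {
    abort_config("lp_order must be even (cascade of second-order sections)")
  }
  check_number(g3, "g3", lower = 0, strict_lower = TRUE)
  if (g3 >= 2) {
    abort_config("g3 must be < 2: the twin-T quality factor 1/(2(2-G)) is undefined or non-positive otherwise")
  }
  structure(
    list(g1 = g1, r_gain = r_gain, f_hp = f_hp,
         lp_order = as.integer(lp_order), f_lp = f_lp, g2 = g2,
         f_notch = f_notch, g3 = g3, ra = ra, rb = rb),
    class = "frontend_config")
}

#' ADC configuration
#'
#' Parameters of the bipolar successive-approximation converter: a 16-bit
#' two's-complement code over a symmetric `c(-v_range, +v_range)` span,
#' sampling the four conditioned channels at 2 kHz.  The +-5 V default span
#' matches a 2 mV peak-to-peak electrode signal after the 2492 V/V cascade.
#'
#' @param bits Resolution in bits (8--24).
#' @param v_range Half of the symmetric full-scale span, in volts.
#' @param fs_adc Sampling rate in Hz.
#' @param n_channels Channels sampled per conversion.
#' @return An object of class `adc_config`.
#' @seealso [quantize()], [dequantize()], [throughput()]
#' @export
adc_config <- function(bits = 16, v_range = 5, fs_adc = 2000,
                       n_channels = 4) {
  check_number(bits, "bits", lower = 8, upper = 24)
  check_number(v_range, "v_range", lower = 0, strict_lower = TRUE)
  check_number(fs_adc, "fs_adc", lower = 0, strict_lower = TRUE)
  check_number(n_channels, "n_channels", lower = 1)
  structure(
    list(bits = as.integer(bits), v_range = v_range, fs_adc = fs_adc,
         n_channels = as.integer(n_channels)),
    class = "adc_config")
}

#' Acquisition-frame layout
#'
#' The 112-bit frame carried over the radio link: a 16-bit sync word, one
#' 16-bit two's-complement sample per channel, and a 32-bit trailer holding a
#' 24-bit rolling frame counter plus an 8-bit longitudinal parity byte (XOR
#' of all payload and counter bytes, i.e. even parity per bit lane).  The
#' 16 + 16x4 + 32 split is fixed by the link-budget arithmetic
#' 2000 Hz x 112 bit = 224,000 bit/s; the sync word and trailer layout are a
#' protocol dialect of this implementation.
#'
#' @param header_bits Sync-word width in bits.
#' @param payload_bits_per_channel Sample width in bits.
#' @param trailer_bits Trailer width in bits (`counter_bits + parity_bits`).
#' @param sync_word Integer value of the sync word (default `0xAA55`).
#' @param counter_bits Rolling-counter width in bits.
#' @param parity_bits Parity-field width in bits.
#' @param n_channels Channels per frame.
#' @return An object of class `frame_spec`.
#' @seealso [pack_frame()], [encode_stream()], [decode_stream()]
#' @export
frame_spec <- function(header_bits = 16, payload_bits_per_channel = 16,
                       trailer_bits = 32, sync_word = 0xAA55,
                       counter_bits = 24, parity_bits = 8,
                       n_channels = 4) {
  if (header_bits %% 8 || payload_bits_per_channel %% 8 || trailer_bits %% 8) {
    abort_config("frame fields must be whole bytes")
  }
  if (counter_bits + parity_bits != trailer_bits) {
    abort_config("counter_bits + parity_bits must equal trailer_bits")
  }
  structure(
    list(header_bits = as.integer(header_bits),
         payload_bits_per_channel = as.integer(payload_bits_per_channel),
         trailer_bits = as.integer(trailer_bits),
         sync_word = as.integer(sync_word),
         counter_bits = as.integer(counter_bits),
         parity_bits = as.integer(parity_bits),
         n_channels = as.integer(n_channels)),
    class = "frame_spec")
}

frame_bits <- function(spec) {
  spec$header_bits + spec$payload_bits_per_channel * spec$n_channels +
    spec$trailer_bits
}

frame_bytes <- function(spec) frame_bits(spec) %/% 8L

#' Fatigue-analysis parameters
#'
#' @param rms_window RMS window length in samples (non-overlapping windows;
#'   2000 samples = 1 s at the 2 kHz acquisition rate).
#' @param stft_window STFT window length in samples (Hann).
#' @param stft_overlap STFT overlap fraction in `[0, 1)`.
#' @param mf_band Two-element Hz interval over which the median frequency is
#'   computed.
#' @param boundary_method How active (force) windows are found:
#'   `"two_means"` (1-D two-means split initialised at the min and max) or
#'   `"threshold"` (above the min/max midpoint).
#' @param rms_norm Per-channel normalization of the RMS series: `"max"`
#'   (divide by the channel maximum, series in `[0, 1]`) or `"sum"`.
#' @return An object of class `fatigue_params`.
#' @seealso [fatigue_report()], [windowed_rms()], [stft_mf()]
#' @export
fatigue_params <- function(rms_window = 2000, stft_window = 2000,
                           stft_overlap = 0.5, mf_band = c(15, 500),
                           boundary_method = c("two_means", "threshold"),
                           rms_norm = c("max", "sum")) {
  check_number(rms_window, "rms_window", lower = 2)
  check_number(stft_window, "stft_window", lower = 4)
  check_number(stft_overlap, "stft_overlap", lower = 0)
  if (stft_overlap >= 1) abort_config("stft_overlap must be in [0, 1)")
  if (length(mf_band) != 2L || mf_band[1] <= 0 || mf_band[1] >= mf_band[2]) {
    abort_config("mf_band must be an increasing positive Hz interval")
  }
  structure(
    list(rms_window = as.integer(rms_window),
         stft_window = as.integer(stft_window),
         stft_overlap = stft_overlap, mf_band = mf_band,
         boundary_method = match.arg(boundary_method),
         rms_norm = match.arg(rms_norm)),
    class = "fatigue_params")
}
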