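#' Generate synthetic surface EMG
#'
#' Produces a multichannel trace whose per-channel carrier is zero-mean
#' Gaussian noise shaped by a fourth-order band-pass (two second-order
#' corners at `band_low` and `band_high`).  Fatigue compresses both corners
#' by `c(t) = 1 - fatigue_compress_rate * t`, applied piecewise over short
#' blocks, which scales the whole spectrum -- and hence the median frequency
#' -- by `c(t)`.  The carrier is normalised block-wise to unit RMS and scaled
#' so that its 99.9% excursion matches the burst envelope
#' `e(t) = (base_amplitude / 2) * (1 + fatigue_amp_rate * t) * burst(t)`,
#' giving a peak-to-peak amplitude close to `base_amplitude` during a
#' full-effort burst.  Bursts are rectangular with 10 ms raised-cosine ramps.
#' Power-line pickup (shared phase across channels), low-frequency drift and
#' white sensor noise are then added.  All randomness derives from
#' `config$seed` through independent substreams, so the output is
#' bit-reproducible.
#'
#' @param config A [synth_config()].
#' @return An [new_emg_trace()] with `n_channels` channels at `fs_synth`.
#' @export
generate_semg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  gen_core(config, channel_gains = rep(1, config$n_channels),
           seed = config$seed)
}

#' Generate a fatiguing-contraction session
#'
#' As [generate_semg()] but requires strictly positive fatigue rates, so the
#' expected windowed RMS grows and the expected median frequency falls over
#' the session -- the canonical myoelectric signature of muscle fatigue.
#'
#' @inheritParams generate_semg
#' @return An `emg_trace`.
#' @export
generate_fatigue_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$fatigue_amp_rate <= 0 || config$fatigue_compress_rate <= 0) {
    abort_config("a fatigue session needs fatigue_amp_rate > 0 and fatigue_compress_rate > 0")
  }
  generate_semg(config)
}

#' Default configuration of an intermittent-force fatigue session
#'
#' One minute of 2 s force cycles (1 s of force), amplitude growing 2% per
#' second and band corners compressing 0.5% per second.
#'
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
fatigue_session_config <- function(seed = 1L) {
  synth_config(duration = 60, fatigue_amp_rate = 0.02,
               fatigue_compress_rate = 0.005,
               burst_period = 2, burst_duration = 1, seed = seed)
}

#' Default per-class channel activation patterns
#'
#' Rows are the four gestures (1 = fist clench, 2 = hand open, 3 = wrist
#' flexion, 4 = wrist extension), columns the four forearm channels; entries
#' are relative envelope gains.  The fist/open rows are deliberately the
#' closest pair, so the distance-ordered tree merges them first.
#'
#' @return A 4 x 4 numeric matrix with gesture row names.
#' @export
default_activation_matrix <- function() {
  m <- rbind(fist      = c(1.0, 0.6, 0.3, 0.3),
             open      = c(0.6, 1.0, 0.6, 0.3),
             flexion   = c(0.3, 0.4, 1.0, 0.5),
             extension = c(0.3, 0.3, 0.5, 1.0))
  colnames(m) <- paste0("ch", 1:4)
  m
}

#' Default generator configuration for gesture trials
#'
#' One-second continuous-effort trials generated directly at the 2 kHz
#' acquisition rate.  Gesture trials emulate conditioned signals referred
#' back to electrode scale, so power-line and drift terms (removed by the
#' notch and high-pass in hardware) default to zero and only the white
#' sensor-noise floor remains.
#'
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
gesture_config <- function(seed = 1L) {
  synth_config(fs_synth = 2000, duration = 1,
               burst_period = 1, burst_duration = 1,
               powerline_amp = 0, drift_amp = 0, noise_amp = 2e-4,
               seed = seed)
}

#' Generate a labelled four-gesture dataset
#'
#' Each trial is a burst trace whose per-channel envelope amplitude is
#' `base_amplitude / 2 * activation_matrix[class, channel] * separability`,
#' jittered by a per-trial lognormal effort factor (sdlog 0.15, shared
#' across channels, emulating trial-to-trial effort variability), plus the
#' configured sensor noise.  Classes are balanced and the whole dataset is
#' deterministic given `config$seed`.
#'
#' @param config A [synth_config()]; see [gesture_config()] for the default
#'   study conditions.
#' @param activation_matrix 4 x `n_channels` nonnegative gain matrix with
#'   distinct rows; identical rows trigger a warning (classes not separable
#'   by construction).
#' @param n_trials_per_class Trials per gesture class.
#' @param separability Scales inter-class contrast relative to the additive
#'   noise floor.
#' @return A `gesture_dataset`: list of trial traces, integer labels in
#'   1..4, the activation matrix and the generating configuration.
#' @export
generate_gesture_dataset <- function(config = gesture_config(),
                                     activation_matrix = default_activation_matrix(),
                                     n_trials_per_class = 40,
                                     separability = 3) {
  stopifnot(inherits(config, "synth_config"))
  activation_matrix <- as.matrix(activation_matrix)
  if (nrow(activation_matrix) != 4L ||
      ncol(activation_matrix) != config$n_channels) {
    abort_config("activation_matrix must be 4 x n_channels")
  }
  if (any(activation_matrix < 0)) {
    abort_config("activation gains must be nonnegative")
  }
  if (anyDuplicated(as.data.frame(activation_matrix))) {
    rlang::warn("activation_matrix has identical rows: classes are not separable by construction")
  }
  check_number(separability, "separability", lower = 0, strict_lower = TRUE)
  check_number(n_trials_per_class, "n_trials_per_class", lower = 0)

  n_trials <- 4L * as.integer(n_trials_per_class)
  labels <- rep(1:4, each = n_trials_per_class)
  trial_seeds <- substream_seeds(config$seed, n_trials + 1L)
  jitters <- withr::with_seed(trial_seeds[n_trials + 1L],
                              stats::rlnorm(max(n_trials, 1L),
                                            meanlog = 0, sdlog = 0.15))
  traces <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    gains <- activation_matrix[labels[i], ] * separability * jitters[i]
    traces[[i]] <- gen_core(config, channel_gains = gains,
                            seed = trial_seeds[i])
  }
  structure(
    list(traces = traces, labels = labels,
         activation_matrix = activation_matrix,
         separability = separability, subject_id = 1L, config = config),
    class = "gesture_dataset")
}

#' @export
print.gesture_dataset <- function(x, ...) {
  cat(sprintf(
    "# gesture_dataset: %d trials (%s), %d channels, separability %g\n",
    length(x$traces),
    paste(table(factor(x$labels, levels = 1:4)), collapse = "/"),
    ncol(x$activation_matrix), x$separability))
  invisible(x)
}

# ---- internals -------------------------------------------------------------

# rectangular burst gate with raised-cosine ramps (ramp shortened for very
# short bursts); returns values in [0, 1]
burst_gate <- function(t, period, duration, ramp = 0.01) {
  if (duration >= period) return(rep(1, length(t)))
  if (duration <= 0) return(rep(0, length(t)))
  ramp <- min(ramp, duration / 2)
  phase <- t %% period
  x <- pmin(pmin(phase, duration - phase) / ramp, 1)
  x <- pmax(x, 0)
  0.5 * (1 - cos(pi * x)) * (phase < duration)
}

# band-shaped unit-RMS Gaussian carrier with piecewise corner compression
shaped_carrier <- function(n, fs, lo, hi, gamma, seed,
                           block_sec = 0.5, ctx_sec = 0.2) {
  white <- withr::with_seed(seed, stats::rnorm(n))
  # two cascaded two-corner band-pass sections: steep enough skirts to keep
  # >= 90% of the power inside [lo, hi] while staying numerically robust
  shape <- function(x, corners) {
    bp <- signal::butter(2, corners / (fs / 2), "pass")
    as.numeric(signal::filter(bp$b, bp$a,
                              signal::filter(bp$b, bp$a, x)))
  }
  if (gamma == 0) {
    y <- shape(white, c(lo, hi))
    return(y / stats::sd(y))
  }
  block <- max(2L, as.integer(round(block_sec * fs)))
  ctx <- as.integer(round(ctx_sec * fs))
  y <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    cs <- max(1L, s - ctx)
    c_t <- 1 - gamma * (((s + e) / 2 - 1) / fs)
    seg <- shape(white[cs:e], c(lo, hi) * c_t)
    kept <- seg[(s - cs + 1L):(e - cs + 1L)]
    y[s:e] <- kept / stats::sd(kept)
  }
  y
}

# shared generator core; channel_gains multiplies the burst envelope per
# channel (1 for plain sEMG, activation x separability x jitter for gestures)
gen_core <- function(config, channel_gains, seed) {
  nch <- config$n_channels
  fs <- config$fs_synth
  n <- as.integer(round(fs * config$duration))
  if (n == 0L) {
    return(new_emg_trace(matrix(numeric(0), nrow = 0, ncol = nch), fs))
  }
  t <- (seq_len(n) - 1) / fs
  seeds <- substream_seeds(seed, 3L * nch + 1L)
  gate <- burst_gate(t, config$burst_period, config$burst_duration)
  env <- (config$base_amplitude / 2) *
    (1 + config$fatigue_amp_rate * t) * gate
  phi <- withr::with_seed(seeds[3L * nch + 1L], stats::runif(1, 0, 2 * pi))
  powerline <- if (config$powerline_amp > 0) {
    config$powerline_amp * sin(2 * pi * config$powerline_freq * t + phi)
  } else 0
  crest <- gaussian_crest()
  out <- matrix(0, nrow = n, ncol = nch)
  for (ch in seq_len(nch)) {
    carrier <- shaped_carrier(n, fs, config$band_low, config$band_high,
                              config$fatigue_compress_rate, seeds[ch])
    x <- (carrier / crest) * env * channel_gains[ch]
    if (config$drift_amp > 0) {
      dw <- withr::with_seed(seeds[nch + ch], stats::rnorm(n))
      lp <- signal::butter(2, min(config$drift_corner / (fs / 2), 0.99))
      d <- as.numeric(signal::filter(lp$b, lp$a, dw))
      x <- x + d * (config$drift_amp / stats::sd(d))
    }
    if (config$noise_amp > 0) {
      x <- x + withr::with_seed(seeds[2L * nch + ch],
                                stats::rnorm(n, sd = config$noise_amp))
    }
    out[, ch] <- x + powerline
  }
  new_emg_trace(out, fs)
}
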