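#' Discretize a continuous transfer function
#'
#' Bilinear transform of an `emg_tf` at rate `fs`, with optional frequency
#' prewarping so the discrete response matches the continuous one exactly at
#' `f_warp` (the notch center for stage 3, the low-pass corner for stage 2).
#'
#' @param tf An `emg_tf`.
#' @param fs Sampling rate in Hz.
#' @param f_warp Prewarp frequency in Hz, or `NULL` for the plain transform.
#' @return A `signal::Arma` digital filter.
#' @export
discretize_tf <- function(tf, fs, f_warp = NULL) {
  stopifnot(inherits(tf, "emg_tf"))
  t_eff <- if (is.null(f_warp) || f_warp <= 0) {
    1 / fs
  } else {
    w <- 2 * pi * f_warp
    2 * tan(w / (2 * fs)) / w
  }
  nd <- length(tf$den) - 1L
  zeros <- if (length(tf$num) > 1L) polyroot(rev(tf$num)) else complex(0)
  poles <- if (nd > 0L) polyroot(rev(tf$den)) else complex(0)
  gain <- Re(tf$num[1] / tf$den[1])
  # pad relative degree: zeros at infinity map to z = -1 under the bilinear
  # transform; signal::bilinear handles that internally
  signal::as.Arma(signal::bilinear(zeros, poles, gain, T = t_eff))
}

# the three discretized stages, each prewarped at its own critical frequency
frontend_filters <- function(config, fs) {
  list(discretize_tf(tf_stage1(config), fs, f_warp = config$f_hp),
       discretize_tf(tf_stage2(config), fs, f_warp = config$f_lp),
       discretize_tf(tf_stage3(config), fs, f_warp = config$f_notch))
}

#' Apply the analog conditioning chain to a trace
#'
#' Runs every channel through the discretized three-stage cascade
#' (amplifier + high-pass, Butterworth low-pass, twin-T notch).  The trace
#' must be sampled at or above `10 * f_lp` so the bilinear models stay
#' faithful to the continuous design; after a start-up transient of
#' `5 / f_hp` seconds, steady-state sinusoid gains match the continuous
#' [freq_response()] to within 1% for frequencies up to `f_lp`.
#'
#' @param trace An `emg_trace` at the synthesis rate.
#' @param config A [frontend_config()].
#' @return The conditioned `emg_trace` at the same rate.
#' @export
apply_frontend <- function(trace, config = frontend_config()) {
  fs <- trace_fs(trace)
  if (fs < 10 * config$f_lp) {
    rlang::abort(sprintf(
      "trace rate %g Hz too low for the analog model: need at least %g Hz (10 x f_lp)",
      fs, 10 * config$f_lp))
  }
  filts <- frontend_filters(config, fs)
  mat <- trace_matrix(trace)
  for (f in filts) {
    mat <- apply(mat, 2, function(x) as.numeric(signal::filter(f$b, f$a, x)))
    mat <- matrix(mat, ncol = ncol(trace) - 1L)
  }
  new_emg_trace(mat, fs, t0 = if (nrow(trace)) trace$time[1] else 0)
}
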