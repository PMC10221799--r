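#' Continuous-domain transfer functions
#'
#' An `emg_tf` holds a rational transfer function H(s) as real numerator and
#' denominator coefficients in decreasing powers of the complex frequency s.
#' Construction checks properness (denominator degree >= numerator degree)
#' and stability (all poles strictly in the left half-plane; zeros may sit on
#' the imaginary axis, as the notch's do).
#'
#' @param num,den Real coefficient vectors, decreasing powers of s.
#' @return An object of class `emg_tf`.
#' @seealso [tf_stage1()], [tf_cascade()], [freq_response()]
#' @export
new_emg_tf <- function(num, den) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  num <- num[cumsum(num != 0) > 0 | seq_along(num) == length(num)]
  den <- den[cumsum(den != 0) > 0 | seq_along(den) == length(den)]
  if (length(den) < 1L || all(den == 0)) rlang::abort("invalid denominator")
  if (length(num) > length(den)) {
    rlang::abort("improper transfer function: numerator degree exceeds denominator degree")
  }
  if (length(den) > 1L) {
    poles <- polyroot(rev(den))
    if (any(Re(poles) >= -1e-9 * max(abs(poles)))) {
      rlang::abort("unstable transfer function: pole in the right half-plane")
    }
  }
  structure(list(num = num, den = den), class = "emg_tf")
}

#' @export
print.emg_tf <- function(x, ...) {
  cat("# emg_tf: order", length(x$den) - 1L,
      "| DC gain", signif(abs(tf_eval(x, 0)), 6), "\n")
  invisible(x)
}

# H(j 2 pi f), vectorised over f
tf_eval <- function(tf, freqs) {
  s <- 2i * pi * freqs
  polyval_dec(tf$num, s) / polyval_dec(tf$den, s)
}

#' Stage 1: instrumentation amplifier + passive high-pass
#'
#' Ideal flat differential gain `g1` cascaded with a first-order high-pass
#' at `f_hp`, i.e. `H(s) = g1 * s / (s + 2 pi f_hp)`.  DC is blocked; far
#' above the corner the magnitude approaches `g1`.
#'
#' @param config A [frontend_config()].
#' @return An `emg_tf`.
#' @export
tf_stage1 <- function(config = frontend_config()) {
  w <- 2 * pi * config$f_hp
  new_emg_tf(c(config$g1, 0), c(1, w))
}

#' Stage 2: fourth-order Butterworth low-pass
#'
#' Maximally flat low-pass scaled to the -3 dB corner `f_lp` with passband
#' gain `g2`; realised in hardware as two cascaded second-order sections,
#' modelled here as the ideal prototype.  The magnitude follows
#' `g2 / sqrt(1 + (f / f_lp)^(2 * lp_order))`, hence about -40 dB at 1.6 kHz
#' for the 500 Hz fourth-order design.
#'
#' @inheritParams tf_stage1
#' @return An `emg_tf`.
#' @export
tf_stage2 <- function(config = frontend_config()) {
  n <- config$lp_order
  w <- 2 * pi * config$f_lp
  k <- seq_len(n)
  poles <- w * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  den <- Re(poly_from_roots(poles))
  new_emg_tf(config$g2 * w^n, den)
}

#' Stage 3: active twin-T notch
#'
#' `H(s) = G (s^2 + w0^2) / (s^2 + (w0 / Q) s + w0^2)` with `w0 = 2 pi
#' f_notch`, `G = g3` and the twin-T quality factor `Q = 1 / (2 (2 - G))`.
#' The zero pair on the imaginary axis nulls the power-line frequency
#' exactly; the passband gain on both sides of the notch is `G`.
#'
#' @inheritParams tf_stage1
#' @return An `emg_tf`.
#' @export
tf_stage3 <- function(config = frontend_config()) {
  w0 <- 2 * pi * config$f_notch
  q <- notch_q(config$g3)
  new_emg_tf(config$g3 * c(1, 0, w0^2), c(1, w0 / q, w0^2))
}

#' Twin-T notch quality factor
#'
#' `Q = 1 / (2 (2 - G))` for positive-feedback gain `G < 2`; as G approaches
#' 2 the notch becomes arbitrarily sharp.
#'
#' @param g Feedback gain G.
#' @return The quality factor.
#' @export
notch_q <- function(g) {
  check_number(g, "g", lower = 0)
  if (g >= 2) abort_config("Q = 1/(2(2-G)) requires G < 2")
  1 / (2 * (2 - g))
}

#' Cascade transfer functions
#'
#' Polynomial product of the stages, so the cascade magnitude is the product
#' of the stage magnitudes at every frequency.
#'
#' @param ... `emg_tf` objects, or a single list of them.
#' @return An `emg_tf`.
#' @export
tf_cascade <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && !inherits(stages[[1]], "emg_tf")) {
    stages <- stages[[1]]
  }
  if (length(stages) < 1L) rlang::abort("need at least one stage")
  num <- 1
  den <- 1
  for (st in stages) {
    stopifnot(inherits(st, "emg_tf"))
    num <- convolve_poly(num, st$num)
    den <- convolve_poly(den, st$den)
  }
  new_emg_tf(num, den)
}

#' The full three-stage conditioning chain
#'
#' @inheritParams tf_stage1
#' @return An `emg_tf` of the cascaded chain, nominal passband gain
#'   `g1 * g2 * g3` (2492 V/V with the defaults).
#' @export
tf_frontend <- function(config = frontend_config()) {
  tf_cascade(tf_stage1(config), tf_stage2(config), tf_stage3(config))
}

#' Frequency response of a transfer function
#'
#' Evaluates `H(j 2 pi f)` exactly from the rational form.
#'
#' @param tf An `emg_tf`.
#' @param freqs Frequencies in Hz (nonnegative).
#' @return A tibble with columns `freq` (Hz), `h` (complex), `gain` (V/V),
#'   `gain_db` (dB) and `phase` (radians).
#' @export
freq_response <- function(tf, freqs) {
  stopifnot(inherits(tf, "emg_tf"), all(freqs >= 0))
  h <- tf_eval(tf, freqs)
  tibble::tibble(freq = freqs, h = h, gain = Mod(h),
                 gain_db = db(Mod(h)), phase = Arg(h))
}

#' Bode table of the conditioning chain
#'
#' Log-spaced frequency response of each stage and of the cascade, the
#' quantity plotted as the logarithmic amplitude-frequency characteristic of
#' the hardware.
#'
#' @param config A [frontend_config()].
#' @param fmin,fmax Frequency range in Hz.
#' @param points Number of log-spaced points.
#' @return A tibble with columns `freq`, `stage`, `gain`, `gain_db`,
#'   `phase`.
#' @export
bode_table <- function(config = frontend_config(), fmin = 1, fmax = 5000,
                       points = 500) {
  freqs <- 10^seq(log10(fmin), log10(fmax), length.out = points)
  stages <- list(stage1 = tf_stage1(config), stage2 = tf_stage2(config),
                 stage3 = tf_stage3(config), cascade = tf_frontend(config))
  purrr::imap_dfr(stages, function(tf, nm) {
    dplyr::mutate(freq_response(tf, freqs)[c("freq", "gain", "gain_db",
                                             "phase")],
                  stage = nm, .after = "freq")
  })
}

#' Bode plot
#'
#' @param table A [bode_table()] result.
#' @return A ggplot object.
#' @export
plot_bode <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$freq, y = .data$gain_db,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency [Hz]", y = "gain [dB]", colour = NULL)
}

# ---- polynomial helpers ----------------------------------------------------

convolve_poly <- function(a, b) {
  out <- rep(0 * (a[1] + b[1]), length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# monic polynomial coefficients (decreasing powers) from its roots
poly_from_roots <- function(roots) {
  out <- 1
  for (r in roots) out <- convolve_poly(out, c(1, -r))
  out
}
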