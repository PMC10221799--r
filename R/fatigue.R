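#' Windowed RMS of a trace
#'
#' Root-mean-square over consecutive non-overlapping windows of
#' `rms_window` samples (2000 samples = 1 s at the 2 kHz acquisition rate);
#' a trailing partial window is discarded.  Each channel is then normalized
#' -- by its maximum (default, so the series lies in `[0, 1]`) or by its sum
#' -- which removes the electrode-dependent absolute scale the way the
#' hardware's fatigue display does.  An all-zero channel stays all zero and
#' is flagged.
#'
#' @param trace An `emg_trace`.
#' @param params A [fatigue_params()].
#' @return A tibble with columns `channel`, `window` (1-based index),
#'   `time` (window-center seconds), `rms_raw` (volts) and `rms`
#'   (normalized).
#' @export
windowed_rms <- function(trace, params = fatigue_params()) {
  mat <- trace_matrix(trace)
  w <- params$rms_window
  n_win <- nrow(mat) %/% w
  if (n_win < 1L) rlang::abort("trace shorter than one RMS window")
  fs <- trace_fs(trace)
  purrr::map_dfr(seq_len(ncol(mat)), function(ch) {
    x <- mat[seq_len(n_win * w), ch]
    rms <- sqrt(colMeans(matrix(x^2, nrow = w)))
    norm <- switch(params$rms_norm,
                   max = max(rms),
                   sum = sum(rms))
    if (norm == 0) {
      rlang::warn(sprintf("channel %d is all zero; normalized RMS left at 0",
                          ch))
      norm <- 1
    }
    tibble::tibble(channel = ch, window = seq_len(n_win),
                   time = (seq_len(n_win) - 0.5) * w / fs,
                   rms_raw = rms, rms = rms / norm)
  })
}

#' Extract the active (upper-boundary) windows
#'
#' During intermittent force the window RMS values split into an obvious
#' high (force) and low (rest) group.  The default `two_means` method runs a
#' one-dimensional two-means iteration initialised at the series minimum and
#' maximum and returns the indices in the upper cluster; `threshold` returns
#' indices above the min/max midpoint.  If the values show no bimodal
#' structure (largest sorted gap not clearly above the uniform spacing), a
#' warning is raised and the threshold rule is used; if all values are
#' equal, every index is returned with a warning.
#'
#' @param values Numeric vector of window RMS values.
#' @param params A [fatigue_params()] (only `boundary_method` is used).
#' @return Integer indices of the upper-boundary windows.
#' @export
extract_upper_boundary <- function(values, params = fatigue_params()) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) rlang::abort("need at least 4 windows")
  rng <- range(values)
  if (diff(rng) == 0) {
    rlang::warn("all window values equal; returning every index")
    return(seq_along(values))
  }
  method <- params$boundary_method
  if (method == "two_means" && !is_bimodal(values)) {
    rlang::warn("no clear force/rest bimodality; falling back to the midpoint threshold")
    method <- "threshold"
  }
  if (method == "threshold") {
    return(which(values > mean(rng)))
  }
  km <- stats::kmeans(values, centers = matrix(rng, ncol = 1))
  upper <- which.max(km$centers)
  which(km$cluster == upper)
}

# largest gap between sorted values relative to uniform spacing; a bimodal
# force/rest split leaves a gap many times wider than the mean spacing
is_bimodal <- function(values, ratio = 3) {
  s <- sort(values)
  max(diff(s)) >= ratio * (diff(range(s)) / (length(s) - 1))
}

#' Ordinary least-squares line fit
#'
#' Minimises the summed squared residuals of `y = intercept + slope * x`.
#'
#' @param x,y Numeric vectors of equal length (>= 2), `x` not all equal.
#' @return A list with `slope` and `intercept`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    rlang::abort("need at least two (x, y) points")
  }
  if (diff(range(x)) == 0) rlang::abort("x values are all equal")
  fit <- stats::.lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Median-frequency track from the short-time Fourier transform
#'
#' Hann-windowed STFT with the configured window and overlap; for each
#' frame, the median frequency is the smallest frequency at which the
#' cumulative power within `mf_band` reaches half the band total, with
#' linear interpolation between bins.  Frames with zero power in the band
#' yield `NA` and are excluded from any downstream fit.
#'
#' @param trace An `emg_trace`.
#' @param params A [fatigue_params()].
#' @return A tibble with columns `channel`, `frame`, `time` (frame-center
#'   seconds), `power` (band power) and `mf` (Hz, `NA` for silent frames).
#' @export
stft_mf <- function(trace, params = fatigue_params()) {
  mat <- trace_matrix(trace)
  fs <- trace_fs(trace)
  w <- params$stft_window
  if (nrow(mat) < w) rlang::abort("trace shorter than one STFT window")
  hop <- max(1L, as.integer(round(w * (1 - params$stft_overlap))))
  band <- params$mf_band
  purrr::map_dfr(seq_len(ncol(mat)), function(ch) {
    sg <- signal::specgram(mat[, ch], n = w, Fs = fs,
                           window = signal::hanning(w), overlap = w - hop)
    pow <- Mod(sg$S)^2
    keep <- sg$f >= band[1] & sg$f <= band[2]
    f_band <- sg$f[keep]
    pow <- pow[keep, , drop = FALSE]
    mf <- apply(pow, 2, median_frequency, freqs = f_band)
    tibble::tibble(channel = ch, frame = seq_along(sg$t),
                   time = as.numeric(sg$t) + if (nrow(trace)) trace$time[1] else 0,
                   power = colSums(pow), mf = mf)
  })
}

# interpolated median of a binned power spectrum
median_frequency <- function(power, freqs) {
  total <- sum(power)
  if (total <= 0) return(NA_real_)
  cs <- cumsum(power)
  half <- total / 2
  i <- which(cs >= half)[1]
  if (i == 1L) return(freqs[1])
  freqs[i - 1L] + (half - cs[i - 1L]) / power[i] * (freqs[i] - freqs[i - 1L])
}

#' Full fatigue analysis of a session
#'
#' Composes the windowed-RMS series, upper-boundary (active window)
#' extraction, a least-squares trend fit over the active windows per
#' channel, the STFT median-frequency track, and a trend fit of the
#' channel-averaged median frequency over active frames.  Rising RMS slopes
#' together with a falling MF slope are the fatigue signature.  For an
#' intermittent protocol the MF fit uses only active frames (selected the
#' same way as the RMS boundary); a sustained session with no force/rest
#' bimodality uses all frames.
#'
#' @param trace An `emg_trace` of at least 10 RMS windows.
#' @param params A [fatigue_params()].
#' @return A `fatigue_report` with elements `rms` (tibble), `boundary`
#'   (per-channel index list), `fits` (per-channel tibble with
#'   `rms_slope`, `rms_intercept`), `mf` (tibble), `mf_fit`
#'   (`mf_slope`/`mf_intercept` of the channel-mean track, per frame
#'   index) and `params`.
#' @export
fatigue_report <- function(trace, params = fatigue_params()) {
  if (nrow(trace) < 10L * params$rms_window) {
    rlang::abort("need at least 10 RMS windows for a trend fit")
  }
  rms <- windowed_rms(trace, params)
  by_ch <- split(rms, rms$channel)
  boundary <- purrr::map(by_ch, function(d) {
    extract_upper_boundary(d$rms, params)
  })
  fits <- purrr::imap_dfr(by_ch, function(d, ch) {
    idx <- boundary[[ch]]
    fit <- linear_fit(d$window[idx], d$rms[idx])
    tibble::tibble(channel = as.integer(ch), rms_slope = fit$slope,
                   rms_intercept = fit$intercept,
                   n_active = length(idx))
  })

  mf <- stft_mf(trace, params)
  mf_mean <- dplyr::summarise(
    dplyr::group_by(mf, .data$frame),
    time = .data$time[1], power = mean(.data$power),
    mf = mean(.data$mf), .groups = "drop")
  active_frames <- tryCatch(
    extract_upper_boundary(mf_mean$power, params),
    warning = function(w) seq_len(nrow(mf_mean)))
  sel <- intersect(active_frames, which(!is.na(mf_mean$mf)))
  mf_fit <- linear_fit(mf_mean$frame[sel], mf_mean$mf[sel])
  structure(
    list(rms = rms, boundary = boundary, fits = fits,
         mf = mf, mf_mean = mf_mean, mf_active_frames = sel,
         mf_slope = mf_fit$slope, mf_intercept = mf_fit$intercept,
         params = params),
    class = "fatigue_report")
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat("# fatigue_report\n")
  cat("  RMS slope per channel:",
      paste(signif(x$fits$rms_slope, 3), collapse = ", "), "\n")
  cat("  MF slope (channel mean):", signif(x$mf_slope, 3),
      "Hz per frame\n")
  invisible(x)
}

#' @method tidy fatigue_report
#' @export
tidy.fatigue_report <- function(x, ...) {
  dplyr::mutate(x$fits, mf_slope = x$mf_slope)
}

#' @method glance fatigue_report
#' @export
glance.fatigue_report <- function(x, ...) {
  tibble::tibble(
    n_windows = max(x$rms$window),
    mean_rms_slope = mean(x$fits$rms_slope),
    all_rms_slopes_positive = all(x$fits$rms_slope > 0),
    mf_slope = x$mf_slope,
    fatigue_signature = all(x$fits$rms_slope > 0) && x$mf_slope < 0)
}

#' @method autoplot fatigue_report
#' @export
autoplot.fatigue_report <- function(object, ...) {
  rms <- dplyr::group_by(object$rms, .data$channel)
  rms <- dplyr::mutate(rms, active = .data$window %in%
                         object$boundary[[dplyr::cur_group_id()]])
  rms <- dplyr::ungroup(rms)
  p1 <- ggplot2::ggplot(rms, ggplot2::aes(.data$window, .data$rms)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$active), size = 0.8) +
    ggplot2::geom_abline(
      data = object$fits,
      ggplot2::aes(slope = .data$rms_slope,
                   intercept = .data$rms_intercept)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "window", y = "normalized RMS")
  p1
}
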