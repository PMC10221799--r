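#' Multichannel signal traces
#'
#' An `emg_trace` is a tibble with a `time` column (seconds) and one `ch<i>`
#' column per channel (volts), carrying the sampling rate as an attribute.
#' It is the common currency between the generator, the analog front end,
#' the ADC and the analyses, and pipes through dplyr verbs like any tibble.
#'
#' @param data Numeric matrix, samples x channels, in volts.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `emg_trace`.
#' @export
new_emg_trace <- function(data, fs, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    rlang::abort("trace data must be finite numeric values")
  }
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- nrow(data)
  if (ncol(data) < 1L) rlang::abort("trace needs at least one channel")
  colnames(data) <- paste0("ch", seq_len(ncol(data)))
  out <- tibble::as_tibble(as.data.frame(data))
  out <- tibble::add_column(out,
                            time = t0 + (seq_len(n) - 1) / fs,
                            .before = 1)
  structure(out, fs = fs, class = c("emg_trace", class(out)))
}

#' @rdname new_emg_trace
#' @param x A data frame with a `time` column and channel columns.
#' @export
as_emg_trace <- function(x, fs = NULL) {
  if (inherits(x, "emg_trace") && is.null(fs)) return(x)
  x <- tibble::as_tibble(x)
  if (!"time" %in% names(x)) rlang::abort("need a `time` column")
  if (is.null(fs)) fs <- infer_fs(x$time)
  mat <- as.matrix(x[setdiff(names(x), "time")])
  new_emg_trace(mat, fs, t0 = if (nrow(x)) x$time[1] else 0)
}

# sampling-rate inference with a uniformity check (1 ppm relative tolerance)
infer_fs <- function(time, tol = 1e-6) {
  if (length(time) < 2L) rlang::abort("cannot infer fs from < 2 samples")
  dt <- diff(time)
  step <- stats::median(dt)
  bad <- which(abs(dt - step) > tol * step)
  if (length(bad)) {
    rlang::abort(sprintf(
      "non-uniform sampling: first offending interval at index %d (dt = %g, expected %g)",
      bad[1], dt[bad[1]], step))
  }
  1 / step
}

#' @rdname new_emg_trace
#' @param trace An `emg_trace`.
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' @rdname new_emg_trace
#' @export
trace_matrix <- function(trace) {
  as.matrix(trace[setdiff(names(trace), "time")])
}

#' @rdname new_emg_trace
#' @export
n_channels <- function(trace) ncol(trace) - 1L

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("# emg_trace: %d channel(s), %d samples at %g Hz (%.3f s)\n",
              n_channels(x), nrow(x), trace_fs(x),
              nrow(x) / trace_fs(x)))
  NextMethod()
}

#' Read and write signal traces
#'
#' Traces are stored as delimited text with a header row
#' `time,ch1,...,chN`, time in seconds and values in volts.  On reading, the
#' sampling rate is inferred from the time column and checked for uniformity
#' to 1 ppm; the round trip is lossless at full double precision.
#'
#' @param path File path.
#' @param trace An `emg_trace`.
#' @return `read_trace()` returns an `emg_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- strsplit(header, ",", fixed = TRUE)[[1]]
  if (length(fields) < 2L || fields[1] != "time" ||
      !all(grepl("^ch[0-9]+$", fields[-1]))) {
    rlang::abort(sprintf(
      "line 1 of %s: expected header `time,ch1,...`, got `%s`", path, header))
  }
  tbl <- utils::read.csv(path, colClasses = "numeric")
  as_emg_trace(tbl)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  cols <- lapply(df, function(x) sprintf("%.17g", x))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Decimate a trace to a lower sampling rate
#'
#' Applies an eighth-order Butterworth anti-alias low-pass at
#' `0.45 * fs_out` and keeps every k-th sample, where `k = fs / fs_out` must
#' be an integer.  This models an ideal decimator in front of the ADC.
#'
#' @param trace An `emg_trace`.
#' @param fs_out Target rate in Hz; must divide the trace rate.
#' @return An `emg_trace` at `fs_out`.
#' @export
resample_trace <- function(trace, fs_out) {
  fs <- trace_fs(trace)
  if (fs == fs_out) return(trace)
  k <- fs / fs_out
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    rlang::abort(sprintf(
      "fs = %g Hz is not an integer multiple of fs_out = %g Hz", fs, fs_out))
  }
  k <- as.integer(round(k))
  aa <- signal::butter(8, 0.45 * fs_out / (fs / 2))
  mat <- trace_matrix(trace)
  filt <- apply(mat, 2, function(x) signal::filter(aa$b, aa$a, x))
  filt <- matrix(filt, nrow = nrow(mat))
  idx <- seq(1L, nrow(mat), by = k)
  new_emg_trace(filt[idx, , drop = FALSE], fs_out, t0 = trace$time[1])
}

#' @method autoplot emg_trace
#' @export
autoplot.emg_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "channel", values_to = "volts")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$volts)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time [s]", y = "amplitude [V]")
}
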