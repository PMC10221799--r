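#' Quantize a conditioned trace
#'
#' Models the bipolar successive-approximation converter: mid-tread rounding
#' to two's-complement integer codes, `code = clamp(round(v / LSB),
#' -2^(bits-1), 2^(bits-1) - 1)` with `LSB = 2 v_range / 2^bits`.  A trace
#' sampled above `fs_adc` is first decimated through [resample_trace()]
#' (integer ratio, anti-alias filtered).  Out-of-range samples clamp to the
#' rails and are tallied in the `n_saturated` attribute.
#'
#' @param trace An `emg_trace` at `fs_adc` or an integer multiple of it.
#' @param adc An [adc_config()].
#' @return An integer matrix (samples x channels) of ADC codes, with
#'   attributes `fs` and `n_saturated`.
#' @export
quantize <- function(trace, adc = adc_config()) {
  stopifnot(inherits(adc, "adc_config"))
  trace <- resample_trace(trace, adc$fs_adc)
  v <- trace_matrix(trace)
  lsb <- 2 * adc$v_range / 2^adc$bits
  lo <- -2^(adc$bits - 1)
  hi <- 2^(adc$bits - 1) - 1
  raw_codes <- round(v / lsb)
  n_sat <- sum(raw_codes < lo | raw_codes > hi)
  codes <- pmin(pmax(raw_codes, lo), hi)
  storage.mode(codes) <- "integer"
  structure(codes, fs = adc$fs_adc, n_saturated = n_sat)
}

#' Reconstruct volts from ADC codes
#'
#' Inverse mapping `v = code * LSB`; the quantize/dequantize round trip is
#' within half an LSB for in-range voltages and exact on the code grid.
#'
#' @param codes Integer code matrix or vector.
#' @param adc An [adc_config()].
#' @return Numeric matrix of volts.
#' @export
dequantize <- function(codes, adc = adc_config()) {
  lsb <- 2 * adc$v_range / 2^adc$bits
  out <- unclass(codes) * lsb
  attr(out, "n_saturated") <- NULL
  out
}
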