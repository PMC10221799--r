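# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_config <- function(msg) {
  rlang::abort(msg, class = "emgtwin_config_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort_config(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Derive independent substream seeds from one master seed, so each channel /
# trial consumes its own reproducible stream regardless of the order in which
# other streams are drawn.  Seeds stay below 2^31.
substream_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

# amplitude for which a unit-variance Gaussian stays within +-crest 99.9% of
# the time; used to convert an envelope (half peak-to-peak) into a carrier RMS
gaussian_crest <- function() stats::qnorm(0.9995)

# polynomial evaluation, coefficients in decreasing powers (complex-safe)
polyval_dec <- function(coef, x) {
  out <- rep_len(coef[1] + 0 * x[1], length(x))
  for (c_i in coef[-1]) out <- out * x + c_i
  out
}

db <- function(ratio) 20 * log10(ratio)
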