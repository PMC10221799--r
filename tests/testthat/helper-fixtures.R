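# shared fixtures, built in code at test time

# generator with every interference source off: isolates the carrier
quiet_config <- function(..., seed = 1L) {
  synth_config(powerline_amp = 0, drift_amp = 0, noise_amp = 0,
               seed = seed, ...)
}

# continuous-effort quiet config (burst gate always open)
continuous_config <- function(duration = 2, seed = 1L, ...) {
  quiet_config(duration = duration, burst_period = duration + 1,
               burst_duration = duration + 1, seed = seed, ...)
}

# four well-separated Gaussian blobs in feature space, classes 1 and 2
# deliberately closest; returns a feature_matrix-shaped tibble
blob_features <- function(n_per_class = 30, sd = 0.3, seed = 42,
                          centers = rbind(c(0, 0), c(1.5, 0),
                                          c(0, 6), c(8, 6))) {
  withr::with_seed(seed, {
    rows <- lapply(1:4, function(k) {
      tibble::tibble(
        label = k,
        trial = seq_len(n_per_class) + (k - 1) * n_per_class,
        epoch = 1L,
        f1 = stats::rnorm(n_per_class, centers[k, 1], sd),
        f2 = stats::rnorm(n_per_class, centers[k, 2], sd))
    })
    dplyr::bind_rows(rows)
  })
}

# fraction of periodogram power inside [lo, hi]; smoothed-periodogram (Welch
# style) oracle, independent of the generator's own shaping path
band_power_fraction <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(51, 51),
                          plot = FALSE, taper = 0)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi]) / sum(sp$spec)
}
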