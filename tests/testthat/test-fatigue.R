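test_that("windowed RMS matches closed forms and window-count law", {
  fs <- 2000
  params <- fatigue_params()
  const <- new_emg_trace(matrix(-0.3, nrow = 12000, ncol = 1), fs)
  r <- windowed_rms(const, params)
  expect_identical(nrow(r), 6L)  # floor(12000 / 2000)
  expect_equal(unique(r$rms_raw), 0.3)
  expect_equal(unique(r$rms), 1)

  t <- (0:11999) / fs
  sine <- new_emg_trace(matrix(0.5 * sin(2 * pi * 100 * t), ncol = 1), fs)
  rs <- windowed_rms(sine, params)
  expect_equal(rs$rms_raw, rep(0.5 / sqrt(2), 6), tolerance = 1e-6)

  zero <- new_emg_trace(matrix(0, nrow = 4000, ncol = 1), fs)
  expect_warning(rz <- windowed_rms(zero, params), "all zero")
  expect_equal(rz$rms, c(0, 0))
})

test_that("normalized RMS peaks at 1 and respects the window-count law", {
  tr <- resample_trace(generate_semg(synth_config(duration = 13, seed = 2)),
                       2000)
  r <- windowed_rms(tr)
  counts <- dplyr::summarise(dplyr::group_by(r, channel),
                             n = dplyr::n(), peak = max(rms))
  expect_true(all(counts$n == nrow(tr) %/% 2000))
  expect_equal(counts$peak, rep(1, 4))
})

test_that("upper-boundary extraction separates force from rest", {
  alt <- rep(c(0.1, 0.9), 10)
  expect_identical(extract_upper_boundary(alt), seq(2L, 20L, by = 2L))

  ramp <- seq(0, 1, length.out = 20)
  expect_warning(idx <- extract_upper_boundary(ramp), "bimodality")
  expect_identical(idx, which(ramp > 0.5))

  expect_warning(all_idx <- extract_upper_boundary(rep(0.4, 8)), "equal")
  expect_identical(all_idx, 1:8)

  expect_error(extract_upper_boundary(c(1, 2, 3)), "at least 4")
})

test_that("boundary windows track the generator's burst schedule", {
  # 1 s force / 2 s cycle at 1 s windows: odd windows are bursts
  cfg <- synth_config(duration = 30, burst_period = 2, burst_duration = 1,
                      fatigue_amp_rate = 0.02, fatigue_compress_rate = 0.005,
                      seed = 8)
  tr <- resample_trace(generate_semg(cfg), 2000)
  r <- dplyr::filter(windowed_rms(tr), channel == 1)
  idx <- extract_upper_boundary(r$rms)
  truth <- seq(1, 29, by = 2)
  agreement <- length(intersect(idx, truth)) / length(union(idx, truth))
  expect_gte(agreement, 0.95)
})

test_that("linear_fit solves ordinary least squares", {
  x <- 1:20
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(linear_fit(x, rep(3, 20))$slope, 0, tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), 1:5), "all equal")

  set.seed(4)
  y <- rnorm(100)
  xr <- runif(100)
  f2 <- linear_fit(xr, y)
  # normal-equation oracle
  sxx <- sum((xr - mean(xr))^2)
  slope <- sum((xr - mean(xr)) * (y - mean(y))) / sxx
  expect_equal(f2$slope, slope, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(y) - slope * mean(xr), tolerance = 1e-10)
})

test_that("median frequency matches closed forms and a cumulative-scan oracle", {
  fs <- 2000
  t <- (0:11999) / fs
  tone <- new_emg_trace(matrix(sin(2 * pi * 120 * t), ncol = 1), fs)
  mf <- stft_mf(tone)
  expect_true(all(abs(mf$mf - 120) <= 1))  # within one bin

  set.seed(6)
  noise <- new_emg_trace(matrix(rnorm(3 * 120000), ncol = 3), fs)
  mfn <- stft_mf(noise)
  expect_lt(abs(mean(mfn$mf) - 257.5), 0.05 * 257.5)

  # interpolated median vs stats::approx on the cumulative curve
  for (i in 1:50) {
    set.seed(i)
    p <- runif(200, min = 1e-6)
    f <- sort(runif(200, 10, 500))
    ours <- emgtwin:::median_frequency(p, f)
    oracle <- stats::approx(cumsum(p), f, xout = sum(p) / 2)$y
    expect_equal(ours, oracle, tolerance = 1e-9)
  }

  set.seed(60)
  silent <- new_emg_trace(matrix(c(rep(0, 4000), rnorm(4000)), ncol = 1), fs)
  mfs <- stft_mf(silent, fatigue_params(stft_overlap = 0))
  expect_true(all(is.na(mfs$mf[1:2])))  # zero-power frames are reported NA
  expect_false(is.na(mfs$mf[nrow(mfs)]))
})

test_that("fatigue sessions show rising RMS and falling MF; null sessions do not", {
  cfg <- fatigue_session_config(seed = 21)
  tr <- resample_trace(generate_fatigue_session(cfg), 2000)
  rep_ <- fatigue_report(tr)
  expect_true(all(rep_$fits$rms_slope > 0))
  expect_lt(rep_$mf_slope, 0)
  g <- glance(rep_)
  expect_true(g$fatigue_signature)

  # null bounds frozen from a 20-seed calibration of the default generator
  for (s in 22:24) {
    trn <- resample_trace(generate_semg(synth_config(duration = 60,
                                                     seed = s)), 2000)
    repn <- fatigue_report(trn)
    expect_lt(abs(mean(repn$fits$rms_slope)), 2e-3)
    expect_lt(abs(repn$mf_slope), 0.5)
  }
})

test_that("a sustained 6 s effort yields one contiguous active region", {
  # conditioned-equivalent trace: drift and power line are removed by the
  # analog chain before any fatigue analysis sees the signal
  cfg <- quiet_config(fs_synth = 2000, duration = 12, burst_period = 12,
                      burst_duration = 6, seed = 31)
  rep_ <- fatigue_report(generate_semg(cfg))
  for (idx in rep_$boundary) {
    expect_identical(idx, seq(min(idx), max(idx)))
    expect_lte(max(idx), 6L)
  }
})
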