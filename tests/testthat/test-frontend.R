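fe <- frontend_config()

test_that("stage 1 is a gained first-order high-pass", {
  h1 <- tf_stage1(fe)
  resp <- freq_response(h1, c(0, 15, 300))
  expect_equal(resp$gain[1], 0)
  expect_equal(resp$gain[2], 100 / sqrt(2), tolerance = 1e-12)
  # closed-form first-order magnitude at 300 Hz
  expect_equal(resp$gain[3], 100 / sqrt(1 + (15 / 300)^2), tolerance = 1e-12)
})

test_that("stage 2 matches the Butterworth design points", {
  h2 <- tf_stage2(fe)
  expect_equal(freq_response(h2, 0)$gain, 17.8, tolerance = 1e-12)
  expect_equal(20 * log10(freq_response(h2, 500)$gain / 17.8),
               -10 * log10(2), tolerance = 1e-9)
  # closed-form 4th-order magnitude at the 1.6 kHz stopband point
  expect_equal(freq_response(h2, 1600)$gain,
               17.8 / sqrt(1 + (1600 / 500)^8), tolerance = 1e-9)
  expect_error(frontend_config(lp_order = 3), class = "emgtwin_config_error")
})

test_that("stage 3 realises the twin-T notch with Q = 1/(2(2-G))", {
  expect_equal(notch_q(1.4), 1 / (2 * 0.6), tolerance = 1e-12)
  expect_error(notch_q(2), class = "emgtwin_config_error")
  expect_error(frontend_config(g3 = 2.1), class = "emgtwin_config_error")
  h3 <- tf_stage3(fe)
  resp <- freq_response(h3, c(0, 50))
  expect_equal(resp$gain[1], 1.4, tolerance = 1e-12)
  expect_lt(resp$gain[2], 1e-10)
})

test_that("cascading multiplies magnitudes and keeps the notch zero", {
  casc <- tf_frontend(fe)
  freqs <- 10^seq(0, log10(5000), length.out = 100)
  gain_casc <- freq_response(casc, freqs)$gain
  gain_prod <- freq_response(tf_stage1(fe), freqs)$gain *
    freq_response(tf_stage2(fe), freqs)$gain *
    freq_response(tf_stage3(fe), freqs)$gain
  expect_equal(gain_casc, gain_prod, tolerance = 1e-9)
  expect_lt(freq_response(casc, 50)$gain, 1e-8)
  one <- tf_cascade(tf_stage2(fe))
  expect_equal(one$num / one$num[1], tf_stage2(fe)$num / tf_stage2(fe)$num[1])
})

test_that("any valid configuration yields a stable cascade", {
  set.seed(7)
  for (i in 1:20) {
    cfg <- frontend_config(g1 = runif(1, 10, 500),
                           f_hp = runif(1, 5, 40),
                           f_lp = runif(1, 200, 1000),
                           g2 = runif(1, 1, 30),
                           f_notch = runif(1, 45, 65),
                           g3 = runif(1, 0.5, 1.99))
    expect_s3_class(tf_frontend(cfg), "emg_tf")  # constructor checks poles
  }
})

test_that("the notch sharpens monotonically as G approaches 2", {
  bandwidth <- sapply(c(1.4, 1.7, 1.9, 1.99), function(g) {
    cfg <- frontend_config(g3 = g)
    freqs <- seq(30, 70, by = 0.01)
    gain <- freq_response(tf_stage3(cfg), freqs)$gain
    sum(gain < g / sqrt(2)) * 0.01  # -3 dB width in Hz
  })
  expect_true(all(diff(bandwidth) < 0))
})

test_that("the discretized chain reproduces the analytic gains on sinusoids", {
  fs <- 20000
  t <- (0:(2 * fs - 1)) / fs
  casc <- tf_frontend(fe)
  for (f in c(20, 100, 300)) {
    tr <- new_emg_trace(matrix(1e-3 * sin(2 * pi * f * t), ncol = 1), fs)
    y <- trace_matrix(apply_frontend(tr, fe))[, 1]
    ss <- y[t > 5 / fe$f_hp]
    measured <- (max(ss) - min(ss)) / 2 / 1e-3
    expect_equal(measured, freq_response(casc, f)$gain, tolerance = 0.01)
  }
  # 50 Hz interference lands >= 30 dB below the mid-passband gain
  tr50 <- new_emg_trace(matrix(1e-3 * sin(2 * pi * 50 * t), ncol = 1), fs)
  y50 <- trace_matrix(apply_frontend(tr50, fe))[, 1]
  amp50 <- (max(y50[t > 1]) - min(y50[t > 1])) / 2 / 1e-3
  expect_lt(20 * log10(amp50 / freq_response(casc, 150)$gain), -30)
})

test_that("apply_frontend is linear at zero and guards the sampling rate", {
  z <- new_emg_trace(matrix(0, nrow = 1000, ncol = 2), 20000)
  expect_equal(max(abs(trace_matrix(apply_frontend(z)))), 0)
  slow <- new_emg_trace(matrix(0, nrow = 100, ncol = 1), 2000)
  expect_error(apply_frontend(slow), "5000")
})
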