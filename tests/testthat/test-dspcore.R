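test_that("nyquist_ok is the strict half-rate criterion", {
  expect_true(nyquist_ok(250, 120))
  expect_false(nyquist_ok(125, 120)) # 120 >= 62.5
  for (B in c(0.5, 10, 60, 437)) expect_false(nyquist_ok(2 * B, B)) # strict
  expect_error(nyquist_ok(-1, 10), class = "pwv_invalid_argument")
  expect_error(nyquist_ok(250, 0), class = "pwv_invalid_argument")
})

test_that("alias_frequency folds into [0, fs/2]", {
  expect_equal(alias_frequency(60, 250), 60)
  expect_equal(alias_frequency(120, 125), 5)
  expect_equal(alias_frequency(60, 100), 40)
  set.seed(8)
  f <- runif(200, 0, 2000)
  fs <- runif(200, 1, 500)
  app <- mapply(alias_frequency, f, fs)
  expect_true(all(app >= 0 & app <= fs / 2 + 1e-12))
  expect_error(alias_frequency(60, 0), class = "pwv_invalid_argument")
  expect_error(alias_frequency(-5, 100), class = "pwv_invalid_argument")
})

test_that("resample_bandlimited preserves DC, length convention, and tones", {
  const <- time_series(rep(3.7, 100), fs = 250)
  for (target in c(10000, 600, 125)) {
    out <- resample_bandlimited(const, target)
    pq <- pwvrecon:::rate_ratio(250, target)
    expect_length(out$samples, ceiling(100 * pq$p / pq$q))
    expect_lt(max(abs(out$samples - 3.7)), 1e-9)
  }
  # n = 100 at 250 Hz -> 10 kHz gives 4000 samples (ratio 40)
  expect_length(resample_bandlimited(const, 10000)$samples, 4000L)

  # analytic sine oracle: 2 Hz at 250 Hz for 10 s -> 10 kHz
  tt <- (0:2499) / 250
  hi <- resample_bandlimited(time_series(sin(2 * pi * 2 * tt), fs = 250), 10000)
  th <- ts_times(hi)
  keep <- th >= 0.5 & th <= max(tt) - 0.5
  expect_lt(max(abs(hi$samples[keep] - sin(2 * pi * 2 * th[keep]))), 1e-3)

  expect_error(resample_bandlimited(const, 250 * sqrt(2)), class = "pwv_unsupported_ratio")
  expect_error(resample_bandlimited(time_series(numeric(0), 250), 500),
               class = "pwv_invalid_argument")
})

test_that("round trip 10 kHz -> 250 Hz -> 10 kHz matches the original", {
  cfg <- noiseless_config(duration = 10, heart_rate_bpm = 72, ibi_jitter_sd = 0.02, seed = 3L)
  ref <- generate_recording(cfg, 10000)$prox
  lo <- decimate_ts(ref, 40L)
  back <- resample_bandlimited(lo, 10000)
  k <- 5000L # 0.5 s edge trim
  idx <- (k + 1):(length(ref$samples) - k)
  err <- abs(back$samples[idx] - ref$samples[idx])
  amp <- diff(range(ref$samples[idx]))
  expect_lt(max(err), 0.01 * amp)
  expect_gte(zncc(time_series(ref$samples[idx], 10000),
                  time_series(back$samples[idx], 10000)), 0.99)
})

test_that("aliasing property: out-of-band tones reappear at the folded frequency", {
  fs <- 125
  for (f in c(120, 70, 200)) {
    tt <- (0:(fs * 20 - 1)) / fs
    ts <- time_series(sin(2 * pi * f * tt), fs = fs)
    hi <- resample_bandlimited(ts, 1000)
    segs <- spectral_segments(hi, seg_duration = 5, floor_freq = 0.5)
    expect_equal(segs[[2]]$dominant_freq, alias_frequency(f, fs), tolerance = 0.21)
  }
})

test_that("lowpass10 has unit DC gain, a deep stopband, and zero net shift", {
  expect_lt(max(abs(lowpass10(time_series(rep(2.5, 1000), fs = 250))$samples - 2.5)), 1e-3)

  tone <- time_series(sin(2 * pi * 60 * (0:4999) / 250), fs = 250)
  filt <- lowpass10(tone)
  mid <- 500:4500
  expect_lt(sqrt(mean(filt$samples[mid]^2)) / sqrt(mean(tone$samples^2)), 0.01)

  # noiseless beat (band < 10 Hz): peak time moves <= 1 sample
  cfg <- noiseless_config(duration = 3, heart_rate_bpm = 60)
  fs <- 1000
  raw <- generate_recording(cfg, fs)$prox
  smo <- lowpass10(raw)
  win <- 1000:2000 # around the second beat, clear of edge transients
  expect_lte(abs(which.max(smo$samples[win]) - which.max(raw$samples[win])), 1L)

  expect_error(lowpass10(time_series(rnorm(100), fs = 15), cutoff = 10),
               class = "pwv_invalid_argument")
})

test_that("derivative matches analytic slopes", {
  expect_equal(derivative(time_series(rep(4, 50), fs = 100))$samples, rep(0, 50))
  ramp <- derivative(time_series(3 * (0:99) / 100, fs = 100))
  expect_equal(ramp$samples[2:99], rep(3, 98), tolerance = 1e-12)
  tt <- (0:9999) / 1000
  d <- derivative(time_series(sin(2 * pi * tt), fs = 1000))
  expect_lt(max(abs(d$samples[2:9999] - 2 * pi * cos(2 * pi * tt[2:9999]))), 1e-3)
  expect_error(derivative(time_series(1, fs = 10)), class = "pwv_invalid_argument")
})

test_that("spectral_segments: segmentation, dominance, and degenerate input", {
  cfg <- synth_config(duration = 19, seed = 2L)
  segs <- spectral_segments(generate_recording(cfg, 250)$prox)
  expect_length(segs, 3L) # floor(19 / 5)

  tt <- (0:(250 * 5 - 1)) / 250
  pure <- spectral_segments(time_series(sin(2 * pi * 2 * tt), fs = 250))
  expect_equal(pure[[1]]$dominant_freq, 2, tolerance = 0.2)
  expect_true(all(pure[[1]]$frequencies >= 0 & pure[[1]]$frequencies <= 125))

  flat <- spectral_segments(time_series(rep(1, 250 * 5), fs = 250))
  above <- flat[[1]]$frequencies >= 0.5
  expect_lt(max(flat[[1]]$magnitudes[above]), 1e-9)

  expect_error(spectral_segments(time_series(rnorm(10), fs = 2), seg_duration = 5),
               class = "pwv_invalid_argument")
})

test_that("zncc: frozen example, affine invariance, symmetry, bounds", {
  a <- time_series(c(1, 0, 0), fs = 10)
  b <- time_series(c(0, 1, 0), fs = 10)
  expect_equal(zncc(a, b), -0.5) # direct evaluation of the formula
  x <- time_series(sin(1:50), fs = 10)
  expect_equal(zncc(x, x), 1.0)
  expect_equal(zncc(x, time_series(2 * sin(1:50) + 3, fs = 10)), 1.0)
  set.seed(4)
  for (i in 1:20) {
    u <- time_series(rnorm(40), fs = 10)
    v <- time_series(rnorm(40), fs = 10)
    z <- zncc(u, v)
    expect_equal(z, zncc(v, u))
    expect_true(z >= -1 && z <= 1)
    expect_equal(zncc(time_series(1.7 * u$samples + 0.3, fs = 10), v), z)
  }
  expect_error(zncc(a, time_series(c(1, 2), fs = 10)), class = "pwv_invalid_argument")
  expect_error(zncc(a, time_series(c(2, 2, 2), fs = 10)), class = "pwv_undefined_correlation")
})

test_that("reconstruction_fidelity: identity, decimation round trip, and null", {
  cfg <- noiseless_config(duration = 10, heart_rate_bpm = 66, ibi_jitter_sd = 0.02, seed = 9L)
  ref <- generate_recording(cfg, 10000)$prox
  expect_equal(reconstruction_fidelity(ref, ref), 1.0, tolerance = 1e-9)
  expect_gte(reconstruction_fidelity(ref, decimate_ts(ref, 40L)), 0.99)

  set.seed(10)
  noise <- time_series(rnorm(length(ref$samples)), fs = 10000)
  expect_lt(abs(reconstruction_fidelity(ref, noise)), 0.2)

  short <- time_series(rnorm(1000), fs = 1000)
  expect_error(reconstruction_fidelity(short, short), class = "pwv_insufficient_overlap")
  expect_error(reconstruction_fidelity(decimate_ts(ref, 40L), ref),
               class = "pwv_invalid_argument")
})
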