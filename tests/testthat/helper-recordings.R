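# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# Noise-free, jitter-free configuration: the cleanest stated world, used when
# a test needs analytically predictable beats.
noiseless_config <- function(duration = 10, heart_rate_bpm = 60, ptt_true = 0.008,
                             seed = 1L, grid_phase = 0, ibi_jitter_sd = 0, ...) {
  synth_config(
    duration = duration, heart_rate_bpm = heart_rate_bpm,
    ibi_jitter_sd = ibi_jitter_sd, ptt_true = ptt_true,
    white_sd = 0, mains_amps = numeric(0), drift_amp = 0,
    seed = seed, grid_phase = grid_phase, ...
  )
}

# Grid-exact decimation of a high-rate channel (keep every `by`-th sample).
decimate_ts <- function(ts, by) {
  time_series(ts$samples[seq(1L, length(ts$samples), by = by)],
              fs = ts$fs / by, start_time = ts$start_time,
              band_limit_hint = ts$band_limit_hint)
}

# Continuous-time systolic peak location of the beat starting at `onset`,
# found on a dense grid (independent argmax oracle).
dense_peak_time <- function(config, onset, channel = "prox", step = 1e-5) {
  shift <- if (channel == "dist") config$ptt_true else 0
  tt <- seq(onset + shift + 0.05, onset + shift + 0.3, by = step)
  tt[which.max(eval_clean(config, tt, channel))]
}

# Beat pairs whose proximal peak lies outside the low-pass edge transients.
interior_pairs <- function(res, duration, edge = 0.6) {
  bp <- res$beat_pairs
  bp[bp$prox_time > edge & bp$prox_time < duration - edge, , drop = FALSE]
}
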