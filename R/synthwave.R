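#' Two-Gaussian arterial beat kernel
#'
#' Continuous-time template for one pulse: a dominant systolic Gaussian plus a
#' smaller, later dicrotic Gaussian. The kernel is smooth and effectively
#' band-limited: with `sigma1 >= 0.04` s the Gaussian spectral magnitude at
#' 10 Hz is below 1% of its peak, so a 10 Hz low-pass preserves the waveform.
#'
#' @param a1,mu1,sigma1 Systolic amplitude, center (s), width (s).
#' @param a2,mu2,sigma2 Dicrotic amplitude, center (s), width (s).
#' @return An object of class `"pwv_kernel"`.
#' @examples
#' k <- beat_kernel()
#' tt <- seq(0, 0.8, by = 1e-3)
#' plot(tt, eval_kernel(k, tt), type = "l")
#' @export
beat_kernel <- function(a1 = 1.0, mu1 = 0.15, sigma1 = 0.05,
                        a2 = 0.35, mu2 = 0.40, sigma2 = 0.09) {
  for (nm in c("a1", "mu1", "sigma1", "a2", "mu2", "sigma2")) {
    check_positive_scalar(get(nm), nm)
  }
  if (!(mu1 < mu2)) pwv_abort("invalid_config", "systolic center mu1 must precede dicrotic mu2")
  if (!(a1 > a2)) pwv_abort("invalid_config", "systolic amplitude a1 must dominate dicrotic a2")
  if (sigma1 < 0.04) {
    pwv_abort("invalid_config", "sigma1 < 0.04 s would push pulse energy above the 10 Hz band")
  }
  structure(list(a1 = a1, mu1 = mu1, sigma1 = sigma1,
                 a2 = a2, mu2 = mu2, sigma2 = sigma2),
            class = "pwv_kernel")
}

#' @rdname beat_kernel
#' @param kernel A `pwv_kernel`.
#' @param tau Times relative to beat onset (s); any numeric vector.
#' @export
eval_kernel <- function(kernel, tau) {
  kernel$a1 * exp(-0.5 * ((tau - kernel$mu1) / kernel$sigma1)^2) +
    kernel$a2 * exp(-0.5 * ((tau - kernel$mu2) / kernel$sigma2)^2)
}

#' Synthetic recording configuration
#'
#' Ground-truth parameters for the two-channel synthetic pulse generator. The
#' distal channel is a pure delay of the proximal channel by `ptt_true`
#' seconds; additive disturbances are white noise (independent per channel),
#' mains interference at `mains_freq` and its harmonics (common to both
#' channels), and a slow baseline-wander sinusoid (respiration-like, common to
#' both channels).
#'
#' Defaults describe the emulated acquisition: a ~19 s recording at resting
#' heart rate 75 BPM with 30 ms inter-beat jitter, true PTT 8 ms over a
#' 3.2 cm electrode span (PWV 4 m/s), white noise at 2% of the systolic
#' amplitude, 60 Hz mains at 5% with a 2.5% second harmonic, and 10%
#' baseline wander at 0.2 Hz.
#'
#' @param duration Recording length in seconds (> 0).
#' @param heart_rate_bpm Mean heart rate, beats/min (> 0).
#' @param ibi_jitter_sd Gaussian jitter SD on inter-beat intervals, seconds.
#' @param ptt_true True channel-2 delay in seconds (> 0, shorter than a beat).
#' @param kernel A [beat_kernel()].
#' @param white_sd White-noise SD, amplitude units.
#' @param mains_freq Mains fundamental, Hz.
#' @param mains_amps Amplitudes of the mains fundamental and successive
#'   harmonics (`mains_freq`, `2*mains_freq`, ...). Zero-length disables mains.
#' @param drift_freq,drift_amp Baseline-wander frequency (Hz) and amplitude.
#' @param seed Integer RNG seed (< 2^31 - 1); all randomness derives from it.
#' @param grid_phase Offset of the first sample relative to t = 0, seconds.
#'   Lets tests align a true peak exactly on a low-rate sample.
#'
#' @return An object of class `"pwv_synth_config"`.
#' @export
synth_config <- function(duration = 19,
                         heart_rate_bpm = 75,
                         ibi_jitter_sd = 0.03,
                         ptt_true = 0.008,
                         kernel = beat_kernel(),
                         white_sd = 0.02,
                         mains_freq = 60,
                         mains_amps = c(0.05, 0.025),
                         drift_freq = 0.2,
                         drift_amp = 0.1,
                         seed = 1L,
                         grid_phase = 0) {
  check_positive_scalar(duration, "duration")
  check_positive_scalar(heart_rate_bpm, "heart_rate_bpm")
  check_nonneg_scalar(ibi_jitter_sd, "ibi_jitter_sd")
  check_positive_scalar(ptt_true, "ptt_true")
  if (!inherits(kernel, "pwv_kernel")) pwv_abort("invalid_config", "`kernel` must be a pwv_kernel")
  check_nonneg_scalar(white_sd, "white_sd")
  check_positive_scalar(mains_freq, "mains_freq")
  if (length(mains_amps) && (!is.numeric(mains_amps) || any(mains_amps < 0))) {
    pwv_abort("invalid_config", "`mains_amps` must be non-negative amplitudes")
  }
  check_positive_scalar(drift_freq, "drift_freq")
  check_nonneg_scalar(drift_amp, "drift_amp")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed >= 2^31 - 1) {
    pwv_abort("invalid_config", "`seed` must be a single integer below 2^31 - 1")
  }
  if (!is.numeric(grid_phase) || length(grid_phase) != 1L || !is.finite(grid_phase)) {
    pwv_abort("invalid_config", "`grid_phase` must be a single finite number")
  }
  if (ptt_true >= 60 / heart_rate_bpm) {
    pwv_abort("invalid_config", "ptt_true must be shorter than one inter-beat interval")
  }
  structure(
    list(duration = duration, heart_rate_bpm = heart_rate_bpm,
         ibi_jitter_sd = ibi_jitter_sd, ptt_true = ptt_true, kernel = kernel,
         white_sd = white_sd, mains_freq = mains_freq,
         mains_amps = as.numeric(mains_amps),
         drift_freq = drift_freq, drift_amp = drift_amp,
         seed = as.integer(seed), grid_phase = grid_phase),
    class = "pwv_synth_config"
  )
}

#' Ground-truth beat onset times
#'
#' Beat onsets start at t = 0 and advance by `60/heart_rate_bpm` plus Gaussian
#' jitter (`ibi_jitter_sd`), truncated below at 20% of the nominal interval so
#' onsets stay strictly increasing. Deterministic given `config$seed`; the
#' caller's RNG state is untouched.
#'
#' @param config A [synth_config()].
#' @return Strictly increasing numeric vector of onset times in `[0, duration)`.
#' @export
beat_times <- function(config) {
  stopifnot(inherits(config, "pwv_synth_config"))
  ibi <- 60 / config$heart_rate_bpm
  if (config$ibi_jitter_sd == 0) {
    n_beats <- floor(config$duration / ibi - 1e-9) + 1L
    return((seq_len(n_beats) - 1L) * ibi)
  }
  n_max <- ceiling(config$duration / ibi * 1.5) + 5L
  intervals <- with_seed(config$seed, {
    pmax(ibi + stats::rnorm(n_max, 0, config$ibi_jitter_sd), 0.2 * ibi)
  })
  onsets <- c(0, cumsum(intervals))
  onsets[onsets < config$duration - 1e-12]
}

#' Evaluate the noiseless continuous-time model
#'
#' Evaluates the clean (noise-free) pulse-train model at arbitrary times:
#' `prox(t) = sum_beats kernel(t - onset)` and `dist(t) = prox(t - ptt_true)`.
#' Because the model is continuous, sampling at any rate or grid phase is
#' exact by construction (no dense-grid decimation error).
#'
#' @inheritParams beat_times
#' @param sample_times Numeric vector of evaluation times, seconds.
#' @param channel `"prox"` or `"dist"`.
#' @return Amplitudes at `sample_times` (same length).
#' @export
eval_clean <- function(config, sample_times, channel = c("prox", "dist")) {
  stopifnot(inherits(config, "pwv_synth_config"))
  channel <- match.arg(channel)
  if (!is.numeric(sample_times)) pwv_abort("invalid_argument", "`sample_times` must be numeric")
  if (!length(sample_times)) return(numeric(0))
  if (any(!is.finite(sample_times))) pwv_abort("invalid_argument", "`sample_times` must be finite")
  t_eval <- if (channel == "dist") sample_times - config$ptt_true else sample_times
  onsets <- beat_times(config)
  out <- numeric(length(t_eval))
  for (onset in onsets) {
    out <- out + eval_kernel(config$kernel, t_eval - onset)
  }
  out
}

#' Generate a synthetic two-channel pulse recording
#'
#' Samples the continuous model of [eval_clean()] on the grid
#' `grid_phase + k/fs`, `k = 0, ..., round(duration*fs) - 1`, and adds the
#' configured disturbances. White noise is drawn independently per channel;
#' mains and baseline wander are common-mode (identical in both channels),
#' with seeded random phases. Noise realizations do not depend on the
#' amplitude settings, so a recording with noise equals the noiseless
#' recording plus the scaled noise realization for the same seed.
#'
#' @inheritParams beat_times
#' @param fs Acquisition sampling rate, Hz (> 0).
#' @param distance Electrode separation in meters carried as metadata.
#' @return A [pulse_recording()] whose `provenance` holds the config, the
#'   ground-truth beat onsets, and `ptt_true`.
#' @examples
#' rec <- generate_recording(synth_config(duration = 5, seed = 7), fs = 250)
#' rec
#' @export
generate_recording <- function(config, fs, distance = 0.032) {
  stopifnot(inherits(config, "pwv_synth_config"))
  check_positive_scalar(fs, "fs")
  n <- round(config$duration * fs)
  if (n < 1) pwv_abort("invalid_argument", "duration*fs must yield at least one sample")
  times <- config$grid_phase + (seq_len(n) - 1) / fs
  clean_p <- eval_clean(config, times, "prox")
  clean_d <- eval_clean(config, times, "dist")

  # Noise seed differs from the jitter seed so beat_times() stays consistent.
  # Mains phases are drawn last so that disabling mains (or changing the
  # number of harmonics) leaves the white-noise and drift realizations
  # untouched — required for the additive-linearity property.
  noise <- with_seed(config$seed + 1L, {
    drift_ph <- stats::runif(1, 0, 2 * pi)
    wp <- stats::rnorm(n)
    wd <- stats::rnorm(n)
    mains_ph <- if (length(config$mains_amps)) {
      stats::runif(length(config$mains_amps), 0, 2 * pi)
    } else numeric(0)
    list(wp = wp, wd = wd, mains_ph = mains_ph, drift_ph = drift_ph)
  })
  common <- config$drift_amp * sin(2 * pi * config$drift_freq * times + noise$drift_ph)
  if (length(config$mains_amps)) {
    for (i in seq_along(config$mains_amps)) {
      common <- common + config$mains_amps[i] *
        sin(2 * pi * config$mains_freq * i * times + noise$mains_ph[i])
    }
  }
  hint <- max(10, if (length(config$mains_amps) && any(config$mains_amps > 0))
    config$mains_freq * length(config$mains_amps) else 0)
  prox <- time_series(clean_p + config$white_sd * noise$wp + common,
                      fs = fs, start_time = config$grid_phase, band_limit_hint = hint)
  dist <- time_series(clean_d + config$white_sd * noise$wd + common,
                      fs = fs, start_time = config$grid_phase, band_limit_hint = hint)
  pulse_recording(prox, dist, distance = distance,
                  provenance = list(config = config,
                                    beat_onsets = beat_times(config),
                                    ptt_true = config$ptt_true))
}
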